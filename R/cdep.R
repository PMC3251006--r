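#' Discretised FDR-threshold grid with a linearly decreasing density
#'
#' The threshold l ranges over (0, 1) and is weighted by the density
#' p(l) = -2l + 2, which emphasises small thresholds (where declared genes
#' are mostly true positives). The integral over l is approximated by the
#' rectangular rule on `bins` equal-width bins, evaluated at bin midpoints
#' l = (j - 0.5)/bins; midpoints avoid the degenerate endpoints l = 0 (no
#' gene declared) and l = 1 (likelihood 1 for every gene), and integrate the
#' linear density exactly.
#'
#' @param bins Number of bins (default 100).
#' @return Object of class `threshold_grid` with `l_values`, `weights`
#'   (density at the midpoints) and `bin_width`.
#' @export
threshold_grid <- function(bins = 100L) {
  bins <- as.integer(bins)
  stopifnot(bins >= 1L)
  l <- (seq_len(bins) - 0.5) / bins
  structure(list(l_values = l, weights = -2 * l + 2, bin_width = 1 / bins),
            class = "threshold_grid")
}

#' Assemble gene-by-dataset FDR matrices on the gene universe
#'
#' Collects each dataset's up- and down-regulation FDRs into G x D matrices
#' over the union gene set. A gene absent from a dataset's platform receives
#' that dataset's median observed FDR (per direction) and is flagged as
#' imputed.
#'
#' @param results List of [rankprod_significance()] results (at least two).
#' @param universe A [build_universe()] object covering the same datasets.
#' @return Object of class `fdr_panel` with `genes`, `datasets`, matrices
#'   `fdr_up`, `fdr_down` and logical matrix `imputed`.
#' @export
assemble_fdr_panel <- function(results, universe) {
  stopifnot(length(results) >= 2L, inherits(universe, "gene_universe"))
  ids <- vapply(results, function(r) r$dataset_id, character(1L))
  stopifnot(identical(sort(ids), sort(colnames(universe$membership))))
  genes <- universe$genes
  G <- length(genes); D <- length(results)
  fill <- function(field) {
    m <- matrix(NA_real_, G, D, dimnames = list(genes, ids))
    for (i in seq_len(D)) {
      r <- results[[i]]
      v <- r[[field]]
      m[match(r$genes, genes), i] <- v
      m[is.na(m[, i]), i] <- median(v)
    }
    m
  }
  imputed <- !universe$membership[, ids, drop = FALSE]
  structure(list(genes = genes, datasets = ids,
                 fdr_up = fill("fdr_up"), fdr_down = fill("fdr_down"),
                 imputed = imputed),
            class = "fdr_panel")
}

#' @export
print.fdr_panel <- function(x, ...) {
  cat(sprintf("fdr_panel: %d genes x %d datasets (%d imputed cells)\n",
              length(x$genes), length(x$datasets), sum(x$imputed)))
  invisible(x)
}

#' Number of genes declared significant at a threshold
#'
#' Counts genes with FDR strictly below l in one dataset's column of the
#' panel (imputed cells included).
#'
#' @param panel An [assemble_fdr_panel()] object.
#' @param l Threshold in (0, 1).
#' @param dataset Dataset index or identifier.
#' @param direction `"up"` or `"down"`.
#' @return Integer count d_il.
#' @export
count_significant <- function(panel, l, dataset, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(inherits(panel, "fdr_panel"), l > 0, l < 1)
  col <- panel[[paste0("fdr_", direction)]][, dataset]
  sum(col < l)
}

#' Per-dataset false-positive rate at a threshold
#'
#' Of the d_il genes declared significant at FDR threshold l, about l * d_il
#' are false positives; dividing by the estimated number of non-regulated
#' genes M gives the probability that a non-regulated gene is falsely
#' declared significant. The rate is clamped into
#' `[r_min, 1 - r_min]` so the Bernoulli log-likelihood stays finite (the
#' plug-in estimate can reach 0, or exceed 1 when l * d_il > M).
#'
#' @param d_il Count of significant genes from [count_significant()].
#' @param l Threshold in (0, 1).
#' @param M_not Estimated number of non-regulated genes (>= 1), from
#'   [estimate_not_de_counts()].
#' @param r_min Clamp bound (default 1e-8).
#' @return Estimated rate in `(0, 1)`.
#' @export
false_positive_rate <- function(d_il, l, M_not, r_min = 1e-8) {
  stopifnot(all(M_not >= 1))
  pmin(pmax(l * d_il / M_not, r_min), 1 - r_min)
}

#' Minus log Bernoulli likelihood of a significance pattern
#'
#' Across datasets, a gene's indicator pattern delta (1 = declared
#' significant at the current threshold) has likelihood
#' `prod_i r_i^delta_i * (1 - r_i)^(1 - delta_i)` under pure false positives;
#' Q is its minus log. Large Q means the pattern is unlikely to be produced
#' by false positives alone.
#'
#' @param delta_row 0/1 vector over datasets.
#' @param rates Per-dataset false-positive rates in (0, 1).
#' @return Q >= 0.
#' @export
minus_log_likelihood <- function(delta_row, rates) {
  stopifnot(length(delta_row) == length(rates),
            all(delta_row %in% c(0, 1)), all(rates > 0), all(rates < 1))
  -sum(delta_row * log(rates) + (1 - delta_row) * log1p(-rates))
}

## Per-dataset threshold profiles: d_il, clamped rates and the two cumulative
## weight sums needed to evaluate gene contributions by a single lookup.
dataset_threshold_profile <- function(fdr_col, M_not, grid, r_min = 1e-8) {
  sorted <- sort(fdr_col)
  d <- findInterval(grid$l_values, sorted, left.open = TRUE)  # strict F < l
  r <- false_positive_rate(d, grid$l_values, M_not, r_min)
  w <- grid$weights * grid$bin_width
  list(d = d, r = r,
       cum_sig = cumsum(w * (-log(r))),       # bins where delta = 1
       cum_not = cumsum(w * (-log1p(-r))))    # bins where delta = 0
}

## Gene-by-dataset contribution matrix to EL: gene g's dataset-i term is
## sum over bins of w * Q-contribution, where delta_gil = I(F_gi < l).
el_contributions <- function(panel, mixtures, grid, direction,
                             r_min = 1e-8) {
  fdr <- panel[[paste0("fdr_", direction)]]
  G <- nrow(fdr); D <- ncol(fdr)
  C <- matrix(0, G, D, dimnames = dimnames(fdr))
  for (i in seq_len(D)) {
    M_not <- estimate_not_de_counts(mixtures[[i]], mixtures[[i]]$G, direction)
    prof <- dataset_threshold_profile(fdr[, i], M_not, grid, r_min)
    tot_sig <- prof$cum_sig[length(prof$cum_sig)]
    ## k = number of bins with l <= F, i.e. where the gene is NOT significant
    k <- findInterval(fdr[, i], grid$l_values)
    cum_sig0 <- c(0, prof$cum_sig); cum_not0 <- c(0, prof$cum_not)
    C[, i] <- (tot_sig - cum_sig0[k + 1L]) + cum_not0[k + 1L]
  }
  C
}

#' Expected minus log likelihood over the threshold density
#'
#' Integrates the minus log likelihood Q_g(l) over the threshold density
#' p(l) = -2l + 2 by the rectangular rule on the grid:
#' `EL_g = sum_bins Q_g(l) p(l) bin_width`. The per-(dataset, bin) counts
#' d_il and rates are computed once and shared across genes.
#'
#' @param panel An [assemble_fdr_panel()] object.
#' @param mixtures List of [fit_beta_mixture()] fits, one per dataset, in
#'   panel dataset order, fitted to the matching direction's p-values.
#' @param grid A [threshold_grid()].
#' @param direction `"up"` or `"down"`.
#' @param r_min Rate clamp bound passed to [false_positive_rate()].
#' @return Named per-gene EL vector (>= 0).
#' @export
expected_likelihood <- function(panel, mixtures, grid,
                                direction = c("up", "down"), r_min = 1e-8) {
  direction <- match.arg(direction)
  stopifnot(inherits(panel, "fdr_panel"), inherits(grid, "threshold_grid"),
            length(mixtures) == length(panel$datasets))
  rowSums(el_contributions(panel, mixtures, grid, direction, r_min))
}

#' Permutation FDR for consistent differential expression
#'
#' Builds the null distribution of EL by shuffling each dataset's FDR values
#' over genes, independently per dataset, B times (per-dataset counts d_il,
#' hence the rates, are invariant under these shuffles and are held fixed).
#' For gene g,
#' `FDR_g = (1/B) sum_b #\{g': EL_g <= EL_null_bg'\} / #\{g': EL_g <= EL_g'\}`
#' with inclusive ties (the denominator includes g itself, so it is >= 1);
#' values are reported capped at 1.
#'
#' @inheritParams expected_likelihood
#' @param B Number of panel permutations (>= 1).
#' @param seed Integer seed for the permutation stream (optional).
#' @param return_null Also return the G x B matrix of null EL values (for
#'   diagnostics).
#' @return Named per-gene FDR vector in `[0, 1]`; if `return_null`, a list
#'   with elements `fdr_g`, `EL` and `null_EL`.
#' @export
permutation_fdr <- function(panel, mixtures, grid, B = 100L, seed = NULL,
                            direction = c("up", "down"), r_min = 1e-8,
                            return_null = FALSE) {
  direction <- match.arg(direction)
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("'B' must be >= 1")
  C <- el_contributions(panel, mixtures, grid, direction, r_min)
  EL <- rowSums(C)
  G <- nrow(C); D <- ncol(C)
  null_EL <- matrix(NA_real_, G, B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      el_b <- numeric(G)
      for (i in seq_len(D)) el_b <- el_b + C[sample.int(G), i]
      null_EL[, b] <- el_b
    }
  })
  fdr <- eq4_fdr(EL, null_EL)
  names(fdr) <- rownames(C)
  if (return_null) list(fdr_g = fdr, EL = EL, null_EL = null_EL) else fdr
}

## The permutation-FDR counting rule shared by CDEP and the signature-count
## comparator: larger statistic = more significant, inclusive ties.
eq4_fdr <- function(stat, null_mat) {
  B <- ncol(null_mat)
  pooled <- sort(as.vector(null_mat))
  num <- (length(pooled) - findInterval(stat, pooled, left.open = TRUE)) / B
  sorted_obs <- sort(stat)
  den <- length(stat) - findInterval(stat, sorted_obs, left.open = TRUE)
  pmin(num / den, 1)
}

#' Run the full consistent-differential-expression meta-analysis
#'
#' Orchestrates the whole pipeline on two or more two-condition datasets:
#' per-dataset rank-product significance (permutation p-values and FDRs),
#' assembly of the union-gene FDR panel with median imputation, a Beta
#' mixture fit per dataset and direction to estimate the non-regulated gene
#' counts, the expected minus log likelihood over the FDR-threshold density,
#' and the permutation FDR -- independently for up- and down-regulation.
#'
#' A gene is called up (down) if its meta-level FDR for that direction is at
#' most `fdr_call`; if both directions pass, the smaller FDR wins, with the
#' larger EL breaking ties.
#'
#' @param datasets List of at least two [expression_dataset()] objects with
#'   unique `dataset_id`s.
#' @param n_perm Label permutations per dataset for the rank-product stage.
#' @param B Panel permutations for the meta-level FDR.
#' @param bins Threshold-grid resolution.
#' @param fdr_call Call threshold on the meta-level FDR.
#' @param seed Master seed; per-stage streams are derived from it.
#' @param sampler List of MCMC settings for [fit_beta_mixture()]
#'   (`chains`, `iter`, `burnin`).
#' @param cap_fdr Passed to [rankprod_significance()].
#' @param r_min Rate clamp bound.
#' @param verbose Log stage timings.
#' @return Object of class `cdep_result`: per-gene `EL_up`, `EL_down`,
#'   `fdr_g_up`, `fdr_g_down` and `call` (up / down / none), plus the
#'   intermediate `rankprod` results, `panel`, `mixtures` and `universe` for
#'   reuse and inspection.
#' @export
run_cdep <- function(datasets, n_perm = 100L, B = 100L, bins = 100L,
                     fdr_call = 0.05, seed = NULL,
                     sampler = list(chains = 2L, iter = 4000L, burnin = 2000L),
                     cap_fdr = FALSE, r_min = 1e-8, verbose = FALSE) {
  if (length(datasets) < 2L) {
    stop("meta-analysis needs at least two datasets")
  }
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(what) say("[%6.1fs] %s", proc.time()[["elapsed"]] - t0, what)

  stage("rank-product significance per dataset")
  rp <- lapply(seq_along(datasets), function(i) {
    rankprod_significance(datasets[[i]], n_perm = n_perm,
                          seed = derive_seed(seed, 100L + i),
                          cap_fdr = cap_fdr)
  })
  universe <- build_universe(datasets)
  panel <- assemble_fdr_panel(rp, universe)

  stage("Beta mixture fits")
  fit_dir <- function(i, direction) {
    fit_beta_mixture(rp[[i]][[paste0("pval_", direction)]],
                     dataset_id = rp[[i]]$dataset_id,
                     chains = sampler$chains, iter = sampler$iter,
                     burnin = sampler$burnin,
                     seed = derive_seed(seed, 200L + 2L * i +
                                          (direction == "down")))
  }
  mix_up <- lapply(seq_along(rp), fit_dir, direction = "up")
  mix_down <- lapply(seq_along(rp), fit_dir, direction = "down")

  grid <- threshold_grid(bins)
  stage("expected likelihood and permutation FDR")
  up <- permutation_fdr(panel, mix_up, grid, B = B,
                        seed = derive_seed(seed, 301L), direction = "up",
                        r_min = r_min, return_null = TRUE)
  down <- permutation_fdr(panel, mix_down, grid, B = B,
                          seed = derive_seed(seed, 302L), direction = "down",
                          r_min = r_min, return_null = TRUE)
  stage("done")

  call <- resolve_calls(up$EL, down$EL, up$fdr_g, down$fdr_g, fdr_call)
  structure(
    list(genes = panel$genes,
         EL_up = setNames(up$EL, panel$genes),
         EL_down = setNames(down$EL, panel$genes),
         fdr_g_up = up$fdr_g, fdr_g_down = down$fdr_g,
         call = call, fdr_call = fdr_call, B = B,
         rankprod = rp, panel = panel, universe = universe,
         mixtures = list(up = mix_up, down = mix_down)),
    class = "cdep_result")
}

## up wins over down on smaller FDR; ties broken by larger EL.
resolve_calls <- function(EL_up, EL_down, fdr_up, fdr_down, threshold) {
  up_ok <- fdr_up <= threshold
  down_ok <- fdr_down <= threshold
  call <- rep("none", length(fdr_up))
  call[up_ok & !down_ok] <- "up"
  call[down_ok & !up_ok] <- "down"
  both <- up_ok & down_ok
  if (any(both)) {
    pick_up <- fdr_up[both] < fdr_down[both] |
      (fdr_up[both] == fdr_down[both] & EL_up[both] >= EL_down[both])
    call[both] <- ifelse(pick_up, "up", "down")
  }
  factor(call, levels = c("up", "down", "none"))
}

#' @export
print.cdep_result <- function(x, ...) {
  cat(sprintf(
    "cdep_result: %d genes, %d up / %d down at FDR_g <= %g (B = %d)\n",
    length(x$genes), sum(x$call == "up"), sum(x$call == "down"),
    x$fdr_call, x$B))
  invisible(x)
}

#' @export
as.data.frame.cdep_result <- function(x, ...) {
  data.frame(gene = x$genes, EL_up = unname(x$EL_up),
             EL_down = unname(x$EL_down), fdr_g_up = unname(x$fdr_g_up),
             fdr_g_down = unname(x$fdr_g_down), call = as.character(x$call),
             row.names = NULL)
}

#' @rdname run_cdep
#' @param x A `cdep_result`.
#' @param path Output path for the per-gene tab-delimited summary.
#' @export
write_cdep_result <- function(x, path) {
  stopifnot(inherits(x, "cdep_result"))
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Genes called consistently differentially expressed
#'
#' @param x A [run_cdep()] result (or a comparator's `baseline_result`).
#' @param direction `"any"`, `"up"` or `"down"`.
#' @return Character vector of gene identifiers.
#' @export
called_genes <- function(x, direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  if (direction == "any") x$genes[x$call != "none"]
  else x$genes[x$call == direction]
}
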