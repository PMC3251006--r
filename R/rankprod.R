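#' Pairwise log fold changes between all case-control sample pairs
#'
#' For a dataset with m cases and n controls, forms the H = m * n pairwise
#' comparisons (case value minus control value, a log fold change for
#' log-scale data). Comparisons are enumerated case-major: all controls for
#' the first case, then the second case, and so on, in sample order.
#'
#' @param ds An [expression_dataset()].
#' @return Numeric matrix, genes x H, with columns named `case.vs.control`.
#' @export
pairwise_fold_changes <- function(ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  cases <- which(ds$condition == 1L)
  ctrls <- which(ds$condition == 0L)
  pairs <- expand.grid(ctrl = ctrls, case = cases)[, c("case", "ctrl")]
  fc <- ds$values[, pairs$case, drop = FALSE] -
    ds$values[, pairs$ctrl, drop = FALSE]
  colnames(fc) <- paste0(ds$samples[pairs$case], ".vs.", ds$samples[pairs$ctrl])
  fc
}

#' Rank product of fold-change ranks across comparisons
#'
#' In each comparison, genes are ranked ascending by -fold-change for
#' up-regulation (rank 1 = strongest increase) and ascending by fold-change
#' for down-regulation (rank 1 = strongest decrease); ties receive average
#' ranks. The rank product is the geometric mean of a gene's ranks across all
#' comparisons; small values flag consistently extreme genes.
#'
#' @param fc Comparison matrix from [pairwise_fold_changes()] (genes x H).
#' @param direction `"up"` or `"down"`.
#' @return Per-gene geometric-mean rank, named by gene.
#' @export
rank_product <- function(fc, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(fc), nrow(fc) >= 2L)
  rk_down <- cpp_col_avg_ranks(fc)
  rk <- if (direction == "up") nrow(fc) + 1 - rk_down else rk_down
  out <- exp(rowMeans(log(rk)))
  names(out) <- rownames(fc)
  out
}

## Mean log ranks (both directions) for a label assignment; case_idx/ctrl_idx
## are column indices into ds$values.
mean_log_ranks <- function(values, case_idx, ctrl_idx) {
  cpp_mean_log_ranks(values, as.integer(case_idx), as.integer(ctrl_idx))
}

## All distinct case/control label assignments as a list of case index sets,
## or NULL if there are more than `limit`.
enumerate_labelings <- function(n_samples, m, limit) {
  n_distinct <- choose(n_samples, m)
  if (n_distinct > limit) return(NULL)
  asplit(combn(n_samples, m), 2L)
}

#' Rank-product significance by label permutation
#'
#' Computes per-gene rank products for up- and down-regulation, permutation
#' p-values, and rank-based FDRs for one dataset. Sample labels are permuted
#' (preserving the case/control counts) and rank products recomputed; the
#' p-value of a gene pools the null rank products across all genes:
#' `p_g = (1 + #\{(b, g'): rp_null <= rp_g\}) / (1 + n_perm * G)`, with
#' add-one smoothing so that p > 0. The FDR divides the p-value by the
#' (relative) rank of the gene's rank product:
#' `F_g = p_g * G / rank(rp_g)`, uncapped by default so the quoted estimator
#' is reported as-is; `cap_fdr = TRUE` truncates at 1.
#'
#' When the number of distinct label assignments is at most `n_perm`, all of
#' them are used (exhaustive enumeration) instead of random shuffles.
#'
#' @param ds An [expression_dataset()].
#' @param n_perm Number of label permutations (default 100).
#' @param seed Integer seed for the permutation stream (optional).
#' @param cap_fdr Truncate FDR estimates at 1 (default `FALSE`).
#' @return Object of class `rankprod_result` with per-gene
#'   `gmean_rank_up` / `gmean_rank_down`, `pval_up` / `pval_down`,
#'   `fdr_up` / `fdr_down`, the comparison count `H`, the effective
#'   permutation count `n_perm` and an `exhaustive` flag.
#' @export
rankprod_significance <- function(ds, n_perm = 100L, seed = NULL,
                                  cap_fdr = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"))
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop("'n_perm' must be >= 1")
  G <- length(ds$genes)
  if (G < 2L) stop("need at least two genes")
  S <- ds$m + ds$n
  obs_cases <- which(ds$condition == 1L)
  obs <- mean_log_ranks(ds$values, obs_cases, setdiff(seq_len(S), obs_cases))
  gamma_up <- exp(obs$mean_log_up)
  gamma_down <- exp(obs$mean_log_down)

  labelings <- enumerate_labelings(S, ds$m, n_perm)
  exhaustive <- !is.null(labelings)
  null_up <- null_down <- vector("list", if (exhaustive) length(labelings) else n_perm)
  run_perm <- function(case_idx) {
    mean_log_ranks(ds$values, case_idx, setdiff(seq_len(S), case_idx))
  }
  with_seed(seed, {
    if (exhaustive) {
      for (b in seq_along(labelings)) {
        r <- run_perm(labelings[[b]])
        null_up[[b]] <- r$mean_log_up
        null_down[[b]] <- r$mean_log_down
      }
    } else {
      for (b in seq_len(n_perm)) {
        r <- run_perm(sample.int(S, ds$m))
        null_up[[b]] <- r$mean_log_up
        null_down[[b]] <- r$mean_log_down
      }
    }
  })
  n_eff <- length(null_up)

  pooled_p <- function(obs_log, null_logs) {
    nulls <- sort(unlist(null_logs, use.names = FALSE))
    cnt <- findInterval(obs_log, nulls)          # inclusive: null <= obs
    (1 + cnt) / (1 + length(nulls))
  }
  pval_up <- pooled_p(obs$mean_log_up, null_up)
  pval_down <- pooled_p(obs$mean_log_down, null_down)

  fdr_of <- function(p, gamma) {
    f <- p * G / rank(gamma, ties.method = "average")
    if (cap_fdr) pmin(f, 1) else f
  }
  nm <- ds$genes
  structure(
    list(dataset_id = ds$dataset_id, genes = nm,
         gmean_rank_up = setNames(gamma_up, nm),
         gmean_rank_down = setNames(gamma_down, nm),
         pval_up = setNames(pval_up, nm),
         pval_down = setNames(pval_down, nm),
         fdr_up = setNames(fdr_of(pval_up, gamma_up), nm),
         fdr_down = setNames(fdr_of(pval_down, gamma_down), nm),
         H = ds$m * ds$n, n_perm = n_eff, exhaustive = exhaustive),
    class = "rankprod_result"
  )
}

#' @export
print.rankprod_result <- function(x, ...) {
  cat(sprintf(
    "rankprod_result '%s': %d genes, H = %d comparisons, %d %s permutations\n",
    x$dataset_id, length(x$genes), x$H, x$n_perm,
    if (x$exhaustive) "exhaustive" else "random"))
  invisible(x)
}

#' @rdname rankprod_significance
#' @param x A `rankprod_result`.
#' @param path Output path for a tab-delimited per-gene summary.
#' @export
write_rankprod_result <- function(x, path) {
  stopifnot(inherits(x, "rankprod_result"))
  df <- data.frame(gene = x$genes, gmean_rank_up = x$gmean_rank_up,
                   gmean_rank_down = x$gmean_rank_down,
                   pval_up = x$pval_up, pval_down = x$pval_down,
                   fdr_up = x$fdr_up, fdr_down = x$fdr_down,
                   row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
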