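#' Signature-counting comparator (Meta-Profile)
#'
#' For each dataset a "differential expression signature" is the set of genes
#' with FDR strictly below the threshold l; a gene's score is the number of
#' signatures it appears in (an integer between 0 and D). The null distribution of
#' the score is obtained by shuffling each dataset's FDR column over genes,
#' independently per dataset, and the gene-level FDR uses the same
#' permutation counting rule as the main method, applied to the count
#' statistic (larger = more significant).
#'
#' @param panel An [assemble_fdr_panel()] object.
#' @param l Signature threshold in (0, 1) (default 0.05).
#' @param B Number of panel permutations.
#' @param seed Integer seed (optional).
#' @param direction `"up"` or `"down"`.
#' @param fdr_call Call threshold on the gene-level FDR.
#' @param return_null Also return the G x B null score matrix (diagnostics).
#' @return Object of class `baseline_result` with `method = "meta_profile"`,
#'   per-gene `score`, `fdr_g` and `call`.
#' @export
meta_profile <- function(panel, l = 0.05, B = 100L, seed = NULL,
                         direction = c("up", "down"), fdr_call = 0.05,
                         return_null = FALSE) {
  direction <- match.arg(direction)
  stopifnot(inherits(panel, "fdr_panel"), l > 0, l < 1)
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("'B' must be >= 1")
  sig <- panel[[paste0("fdr_", direction)]] < l
  score <- rowSums(sig)
  G <- nrow(sig); D <- ncol(sig)
  null_scores <- matrix(NA_real_, G, B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      s <- numeric(G)
      for (i in seq_len(D)) s <- s + sig[sample.int(G), i]
      null_scores[, b] <- s
    }
  })
  fdr <- eq4_fdr(score, null_scores)
  names(fdr) <- panel$genes
  out <- structure(
    list(method = "meta_profile", genes = panel$genes,
         score = setNames(score, panel$genes), fdr_g = fdr,
         direction = direction, B = B,
         call = ifelse(fdr <= fdr_call, direction, "none")),
    class = "baseline_result")
  if (return_null) out$null_scores <- null_scores
  out
}

#' Pooled cross-dataset rank product comparator (Meta-RankProd)
#'
#' Pools every case-control comparison of every dataset into one rank
#' product: the per-gene geometric mean of its fold-change ranks across all
#' `sum(H_i)` comparisons. A gene absent from a dataset contributes that
#' dataset's median per-gene rank product once per comparison. The null
#' distribution permutes the expression values within each single array
#' (shuffling gene labels per column, independently per array and
#' permutation) and recomputes the pooled statistic; p-values pool the null
#' across genes with add-one smoothing, and the gene-level FDR divides the
#' p-value by the rank of the statistic (smaller = more significant), capped
#' at 1.
#'
#' Because every comparison carries equal weight, datasets with many samples
#' dominate the pooled statistic -- the behaviour the main method is designed
#' to avoid.
#'
#' @param datasets List of [expression_dataset()] objects.
#' @param universe A [build_universe()] object; if `NULL`, built from
#'   `datasets`.
#' @param B Number of within-array permutations.
#' @param seed Integer seed (optional).
#' @param direction `"up"`, `"down"`, or `"both"` (both directions from the
#'   same permutation draws).
#' @param fdr_call Call threshold on the gene-level FDR.
#' @param return_null Also return the G x B null score matrices (diagnostics).
#' @return Object of class `baseline_result` with `method = "meta_rankprod"`,
#'   per-gene `score` (pooled geometric-mean rank), `fdr_g` and `call`; for
#'   `direction = "both"`, a list with elements `up` and `down`.
#' @export
meta_rankprod <- function(datasets, universe = NULL, B = 100L, seed = NULL,
                          direction = c("up", "down", "both"),
                          fdr_call = 0.05, return_null = FALSE) {
  direction <- match.arg(direction)
  stopifnot(length(datasets) >= 2L)
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("'B' must be >= 1")
  if (is.null(universe)) universe <- build_universe(datasets)
  genes <- universe$genes
  G <- length(genes); D <- length(datasets)
  H <- vapply(datasets, function(d) d$m * d$n, numeric(1L))

  ## pooled mean log rank over all comparisons (both directions), median
  ## imputation for genes absent from a dataset
  pooled_stat <- function(value_list) {
    acc_up <- acc_down <- numeric(G)
    for (i in seq_len(D)) {
      ds <- datasets[[i]]
      r <- mean_log_ranks(value_list[[i]], which(ds$condition == 1L),
                          which(ds$condition == 0L))
      at <- match(ds$genes, genes)
      for (dir in c("up", "down")) {
        ml <- r[[paste0("mean_log_", dir)]]
        full <- rep(log(median(exp(ml))), G)
        full[at] <- ml
        if (dir == "up") acc_up <- acc_up + H[i] * full
        else acc_down <- acc_down + H[i] * full
      }
    }
    list(up = exp(acc_up / sum(H)), down = exp(acc_down / sum(H)))
  }

  score <- pooled_stat(lapply(datasets, `[[`, "values"))
  null_up <- null_down <- matrix(NA_real_, G, B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      shuffled <- lapply(datasets, function(ds) {
        v <- ds$values
        for (j in seq_len(ncol(v))) v[, j] <- v[sample.int(nrow(v)), j]
        v
      })
      s <- pooled_stat(shuffled)
      null_up[, b] <- s$up
      null_down[, b] <- s$down
    }
  })
  one_result <- function(dir, null_scores) {
    sc <- score[[dir]]
    pooled <- sort(as.vector(null_scores))
    pval <- (1 + findInterval(sc, pooled)) / (1 + length(pooled))
    fdr <- pmin(pval * G / rank(sc, ties.method = "average"), 1)
    names(fdr) <- genes
    out <- structure(
      list(method = "meta_rankprod", genes = genes,
           score = setNames(sc, genes), fdr_g = fdr,
           direction = dir, B = B,
           call = ifelse(fdr <= fdr_call, dir, "none")),
      class = "baseline_result")
    if (return_null) out$null_scores <- null_scores
    out
  }
  switch(direction,
         up = one_result("up", null_up),
         down = one_result("down", null_down),
         both = list(up = one_result("up", null_up),
                     down = one_result("down", null_down)))
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("baseline_result (%s, %s): %d genes, %d called\n",
              x$method, x$direction, length(x$genes),
              sum(x$call != "none")))
  invisible(x)
}
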