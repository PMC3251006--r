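# Fixtures and independent oracles used across the test files.

# Small expression dataset with named genes/samples.
make_dataset <- function(values, condition, id = "ds") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  expression_dataset(values, condition, dataset_id = id)
}

# Pure-noise dataset.
noise_dataset <- function(G, m, n, id = "null", seed = 1, sd = 1) {
  set.seed(seed)
  make_dataset(matrix(rnorm(G * (m + n), sd = sd), G, m + n),
               rep(c(1L, 0L), c(m, n)), id = id)
}

# Hand-rolled rank product oracle: base-R ranks, explicit geometric mean.
oracle_rank_product <- function(fc, direction) {
  rk <- apply(if (direction == "up") -fc else fc, 2, rank,
              ties.method = "average")
  exp(rowMeans(log(rk)))
}

# Brute-force rank-product significance with an explicit list of label
# assignments (case index sets). Mirrors the pooled-counting definitions
# directly; independent of the package's C++ path.
oracle_rankprod_exhaustive <- function(ds, labelings) {
  G <- nrow(ds$values)
  fc_of <- function(case_idx) {
    ctrl_idx <- setdiff(seq_along(ds$condition), case_idx)
    fc <- matrix(NA_real_, G, length(case_idx) * length(ctrl_idx))
    h <- 0L
    for (ca in case_idx) for (tb in ctrl_idx) {
      h <- h + 1L
      fc[, h] <- ds$values[, ca] - ds$values[, tb]
    }
    fc
  }
  # work on the mean-log scale so tie comparisons are exact; accumulate in
  # plain double (column by column) so mathematically tied means agree
  # bitwise across implementations
  gam_log <- function(case_idx, direction) {
    fc <- fc_of(case_idx)
    rk <- apply(if (direction == "up") -fc else fc, 2, rank,
                ties.method = "average")
    acc <- numeric(nrow(rk))
    for (h in seq_len(ncol(rk))) acc <- acc + log(rk[, h])
    acc / ncol(rk)
  }
  obs_cases <- which(ds$condition == 1L)
  out <- list()
  for (direction in c("up", "down")) {
    lg_obs <- gam_log(obs_cases, direction)
    nulls <- unlist(lapply(labelings, gam_log, direction = direction))
    p <- vapply(lg_obs, function(x) (1 + sum(nulls <= x)) / (1 + length(nulls)),
                numeric(1))
    fdr <- p * G / rank(lg_obs, ties.method = "average")
    out[[direction]] <- list(gamma = exp(lg_obs), p = p, fdr = fdr)
  }
  out
}

# Brute-force double-loop FDR_g (Eq. 4 style): larger stat = significant,
# inclusive ties, capped at 1.
oracle_eq4 <- function(stat, null_mat) {
  B <- ncol(null_mat)
  vapply(seq_along(stat), function(g) {
    num <- 0
    for (b in seq_len(B)) num <- num + sum(stat[g] <= null_mat[, b])
    min((num / B) / sum(stat[g] <= stat), 1)
  }, numeric(1))
}

# Brute-force EL: per-gene loop over bins and datasets through the exported
# scalar operations, no sharing of per-bin quantities.
oracle_el <- function(panel, mixtures, grid, direction) {
  fdr <- panel[[paste0("fdr_", direction)]]
  M <- vapply(mixtures, function(f) {
    estimate_not_de_counts(f, f$G, direction)
  }, integer(1))
  G <- nrow(fdr); D <- ncol(fdr)
  el <- numeric(G)
  for (g in seq_len(G)) {
    acc <- 0
    for (j in seq_along(grid$l_values)) {
      l <- grid$l_values[j]
      delta <- as.numeric(fdr[g, ] < l)
      r <- vapply(seq_len(D), function(i) {
        false_positive_rate(count_significant(panel, l, i, direction), l, M[i])
      }, numeric(1))
      acc <- acc + minus_log_likelihood(delta, r) * grid$weights[j] *
        grid$bin_width
    }
    el[g] <- acc
  }
  el
}

# Assemble an fdr_panel directly from given matrices (bypasses rank product)
# for targeted aggregation tests.
panel_from_matrices <- function(fdr_up, fdr_down = fdr_up) {
  genes <- rownames(fdr_up)
  ids <- colnames(fdr_up)
  structure(list(genes = genes, datasets = ids, fdr_up = fdr_up,
                 fdr_down = fdr_down,
                 imputed = matrix(FALSE, nrow(fdr_up), ncol(fdr_up),
                                  dimnames = dimnames(fdr_up))),
            class = "fdr_panel")
}

# Mixture-fit stub with a fixed theta (for EL tests that need known M-bar).
mixture_stub <- function(theta, G, id = "stub") {
  structure(list(dataset_id = id, theta = theta,
                 beta_params = cbind(a = c(1, 2, 20), b = c(20, 2, 1)),
                 G = G, n_draws = 0L, rhat = rep(NA_real_, 3),
                 converged = TRUE, accept_rate = NA_real_, n_clamped = 0L,
                 prior_only = FALSE),
            class = "mixture_fit")
}
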