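test_that("pairwise comparisons are enumerated case-major with case minus control", {
  v <- matrix(c(5, 1, 3, 2, 7, 0, 6, 4), 2, 4,
              dimnames = list(c("g1", "g2"), c("c1", "c2", "t1", "t2")))
  ds <- expression_dataset(v, c(1, 1, 0, 0))
  fc <- pairwise_fold_changes(ds)
  expect_equal(dim(fc), c(2L, 4L))
  expect_equal(colnames(fc),
               c("c1.vs.t1", "c1.vs.t2", "c2.vs.t1", "c2.vs.t2"))
  expect_equal(unname(fc["g1", ]), c(5 - 7, 5 - 6, 3 - 7, 3 - 6))
  # single pair
  ds1 <- expression_dataset(v[, c(1, 3)], c(1, 0))
  expect_equal(unname(pairwise_fold_changes(ds1)[, 1]), c(5 - 7, 1 - 0))
  # constant gene gives a zero row
  vz <- rbind(v, g3 = 1)
  dsz <- expression_dataset(vz, c(1, 1, 0, 0))
  expect_equal(unname(pairwise_fold_changes(dsz)["g3", ]), rep(0, 4))
})

test_that("rank product matches hand-computed geometric means of ranks", {
  # single comparison: ranks are just the orderings
  fc <- matrix(c(2, 0, -1), 3, 1)
  expect_equal(unname(rank_product(fc, "up")), c(1, 2, 3))
  expect_equal(unname(rank_product(fc, "down")), c(3, 2, 1))
  # two opposing comparisons: both genes get sqrt(1*2)
  fc2 <- matrix(c(1, -1, -1, 1), 2, 2)
  expect_equal(unname(rank_product(fc2, "up")), c(sqrt(2), sqrt(2)))
  # agrees with a base-R oracle on random data, both directions
  set.seed(7)
  fc3 <- matrix(rnorm(50 * 6), 50, 6)
  for (dir in c("up", "down")) {
    expect_equal(unname(rank_product(fc3, dir)),
                 unname(oracle_rank_product(fc3, dir)))
  }
  expect_gte(min(rank_product(fc3, "up")), 1)
})

test_that("tie-free up and down ranks are complementary per comparison", {
  set.seed(11)
  ds <- noise_dataset(40, 3, 3, seed = 11)
  fc <- pairwise_fold_changes(ds)
  G <- nrow(fc)
  rk_down <- apply(fc, 2, rank, ties.method = "average")
  rk_up <- apply(-fc, 2, rank, ties.method = "average")
  expect_equal(rk_up + rk_down, matrix(G + 1, G, ncol(fc)),
               ignore_attr = TRUE)
  # the C++ path reproduces both directions consistently
  expect_equal(unname(rank_product(fc, "up")),
               unname(exp(rowMeans(log(rk_up)))))
})

test_that("lowering case values never decreases the up rank product", {
  set.seed(3)
  ds <- noise_dataset(30, 2, 3, seed = 3)
  g_up0 <- rank_product(pairwise_fold_changes(ds), "up")
  v2 <- ds$values
  v2[5, ds$condition == 1] <- v2[5, ds$condition == 1] - 2
  ds2 <- expression_dataset(v2, ds$condition, "mod")
  g_up1 <- rank_product(pairwise_fold_changes(ds2), "up")
  expect_gte(g_up1[5], g_up0[5])
})

test_that("exhaustive small-sample permutation matches the brute-force oracle", {
  for (shape in list(c(1, 1), c(2, 2), c(3, 3), c(2, 4))) {
    m <- shape[1]; n <- shape[2]
    ds <- noise_dataset(9, m, n, seed = 17 + m * 10 + n)
    n_distinct <- choose(m + n, m)
    res <- rankprod_significance(ds, n_perm = n_distinct, seed = 5)
    expect_true(res$exhaustive)
    labelings <- asplit(combn(m + n, m), 2)
    oracle <- oracle_rankprod_exhaustive(ds, labelings)
    expect_equal(unname(res$gmean_rank_up), unname(oracle$up$gamma))
    expect_equal(unname(res$pval_up), unname(oracle$up$p))
    expect_equal(unname(res$fdr_up), unname(oracle$up$fdr))
    expect_equal(unname(res$pval_down), unname(oracle$down$p))
    expect_equal(unname(res$fdr_down), unname(oracle$down$fdr))
  }
})

test_that("boundary of the counting formula: globally smallest rank product", {
  # G=3, m=n=1: with a planted dominant gene the observed top gamma is 1 and
  # can only be tied, never beaten, across the 2 label assignments
  ds <- make_dataset(rbind(c(10, 0), c(1.0, 1.1), c(0.9, 1.3)), c(1, 0))
  res <- rankprod_significance(ds, n_perm = 2, seed = 1)
  G <- 3; n_eff <- res$n_perm
  # gene 1 is rank 1 in the observed comparison
  expect_equal(unname(res$gmean_rank_up[1]), 1)
  # pooled counting: nulls <= 1 are the two rank-1 entries of the 2 labelings
  expect_equal(unname(res$pval_up[1]), (1 + 2) / (1 + n_eff * G))
  expect_equal(unname(res$fdr_up[1]), unname(res$pval_up[1]) * G / 1)
})

test_that("null p-values are calibrated in aggregate", {
  ds <- noise_dataset(2000, 3, 3, seed = 23)
  res <- rankprod_significance(ds, n_perm = 200, seed = 29)
  frac <- mean(res$pval_up <= 0.05)
  expect_lt(abs(frac - 0.05), 0.02)   # Monte-Carlo band
  expect_error(rankprod_significance(ds, n_perm = 0), "n_perm")
})

test_that("with signal present, null genes' p-values are not uniform", {
  # the pooled permutation null absorbs the planted effects, so p-values of
  # unregulated genes concentrate away from 0 and 1 -- the non-uniform shape
  # that motivates a free Beta bulk component instead of a uniform null
  cfg <- simulation_config(m = 10, n = 10, G = 2000, p = 0.1, q = 0.1,
                           delta = 1, psi = 0.25, noise_sd = 0.5)
  sim <- simulate_panel(cfg, seed = 23)
  res <- rankprod_significance(sim$datasets[[1]], n_perm = 50, seed = 29)
  null_p <- res$pval_up[sim$truth$category == "N"]
  ks <- suppressWarnings(stats::ks.test(null_p, "punif"))
  expect_lt(ks$p.value, 1e-6)
})

test_that("FDR capping flag truncates at 1 without changing order", {
  ds <- noise_dataset(50, 2, 2, seed = 31)
  r1 <- rankprod_significance(ds, n_perm = 6, seed = 7)
  r2 <- rankprod_significance(ds, n_perm = 6, seed = 7, cap_fdr = TRUE)
  expect_gt(max(r1$fdr_up), 1)        # uncapped estimator exceeds 1
  expect_lte(max(r2$fdr_up), 1)
  expect_equal(pmin(r1$fdr_up, 1), r2$fdr_up)
})
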