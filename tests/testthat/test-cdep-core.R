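test_that("threshold grid integrates the linear density to one", {
  g <- threshold_grid(100)
  expect_equal(length(g$l_values), 100L)
  expect_true(all(diff(g$l_values) > 0))
  expect_true(all(g$l_values > 0 & g$l_values < 1))
  expect_lt(abs(sum(g$weights * g$bin_width) - 1), 1e-6)
  # holds for other resolutions too (midpoint rule is exact for a line)
  for (b in c(10, 37, 250)) {
    expect_lt(abs(sum(threshold_grid(b)$weights / b) - 1), 1e-6)
  }
})

test_that("panel assembly imputes absent genes with the dataset median FDR", {
  d1 <- noise_dataset(7, 2, 2, id = "d1", seed = 1)
  # d2 lacks the last two genes of d1's platform
  set.seed(2)
  v2 <- matrix(rnorm(5 * 4), 5, 4,
               dimnames = list(sprintf("g%03d", 1:5), sprintf("s%02d", 1:4)))
  d2 <- expression_dataset(v2, c(1, 1, 0, 0), "d2")
  rp <- lapply(list(d1, d2), rankprod_significance, n_perm = 10, seed = 3)
  u <- build_universe(list(d1, d2))
  panel <- assemble_fdr_panel(rp, u)
  absent <- setdiff(d1$genes, d2$genes)
  expect_equal(unname(panel$fdr_up[absent, "d2"]),
               rep(median(rp[[2]]$fdr_up), 2))
  expect_true(all(panel$imputed[absent, "d2"]))
  expect_false(any(panel$imputed[, "d1"]))
  expect_false(anyNA(panel$fdr_up))
  expect_false(anyNA(panel$fdr_down))
  # odd column length: the median is the middle order statistic
  expect_equal(median(rp[[2]]$fdr_up), unname(sort(rp[[2]]$fdr_up)[3]))
})

test_that("significance counts use a strict inequality", {
  fdr_up <- matrix(c(0.01, 0.5, 0.9), 3, 1,
                   dimnames = list(c("a", "b", "c"), "d1"))
  panel <- panel_from_matrices(fdr_up)
  expect_equal(count_significant(panel, 0.05, 1, "up"), 1)
  expect_equal(count_significant(panel, 0.01, 1, "up"), 0)   # l <= min(F)
  expect_equal(count_significant(panel, 0.9999, 1, "up"), 3)
  expect_equal(count_significant(panel, 0.5, 1, "up"), 1)    # 0.5 not < 0.5
})

test_that("false-positive rates follow l*d/M with clamping", {
  expect_equal(false_positive_rate(100, 0.05, 9500), 100 * 0.05 / 9500)
  expect_equal(false_positive_rate(0, 0.05, 9500), 1e-8)
  expect_equal(false_positive_rate(1000, 0.9, 10), 1 - 1e-8)
})

test_that("minus log likelihood matches direct arithmetic and the l->1 limit", {
  expect_equal(minus_log_likelihood(c(1, 1), c(0.01, 0.02)),
               -(log(0.01) + log(0.02)))
  expect_lt(minus_log_likelihood(c(0, 0), c(1e-6, 1e-6)), 1e-5)
  # l -> 1 limit: every gene declared, rates at the upper clamp, Q vanishes
  D <- 6
  q_limit <- minus_log_likelihood(rep(1, D), rep(1 - 1e-8, D))
  expect_lt(q_limit, 1e-6)
  expect_gte(q_limit, 0)
})

test_that("EL of a threshold-constant Q equals that Q", {
  g <- threshold_grid(100)
  q <- minus_log_likelihood(c(1, 0, 1), c(0.02, 0.3, 0.01))
  el <- sum(q * g$weights * g$bin_width)
  expect_lt(abs(el - q), 1e-10)
})

test_that("expected likelihood matches the brute-force per-gene oracle", {
  set.seed(5)
  G <- 20; D <- 3
  fdr_up <- matrix(runif(G * D, 0.001, 1.4), G, D,
                   dimnames = list(sprintf("g%03d", 1:G), paste0("d", 1:D)))
  panel <- panel_from_matrices(fdr_up)
  mixtures <- lapply(1:D, function(i) {
    mixture_stub(c(0.06, 0.88, 0.06), G = G, id = paste0("d", i))
  })
  grid <- threshold_grid(100)
  el <- expected_likelihood(panel, mixtures, grid, "up")
  expect_lt(max(abs(el - oracle_el(panel, mixtures, grid, "up"))), 1e-10)
  expect_true(all(el >= 0))
})

test_that("EL ranks consistent patterns above single-dataset patterns", {
  D <- 6
  G <- 50   # mostly unregulated genes, so false-positive rates stay small
  fdr_up <- rbind(consistent = rep(0.001, D),
                  single = c(0.001, rep(0.9, D - 1)),
                  matrix(0.99, G - 2, D,
                         dimnames = list(paste0("dull", 1:(G - 2)), NULL)))
  colnames(fdr_up) <- paste0("d", 1:D)
  panel <- panel_from_matrices(fdr_up)
  mixtures <- lapply(1:D, function(i) mixture_stub(c(0.04, 0.92, 0.04), G = G))
  el <- expected_likelihood(panel, mixtures, threshold_grid(100), "up")
  expect_gt(el[["consistent"]], el[["single"]])
  expect_lt(el[["dull1"]], 0.05)     # never-declared gene has tiny EL
})

test_that("making a gene more significant in one dataset never lowers its EL", {
  set.seed(9)
  G <- 15; D <- 4
  fdr_up <- matrix(runif(G * D, 0.01, 1.2), G, D,
                   dimnames = list(sprintf("g%03d", 1:G), paste0("d", 1:D)))
  mixtures <- lapply(1:D, function(i) mixture_stub(c(0.05, 0.9, 0.05), G = G))
  grid <- threshold_grid(100)
  el0 <- expected_likelihood(panel_from_matrices(fdr_up), mixtures, grid, "up")
  for (g in c(1, 7, 15)) for (i in c(1, 3)) {
    f2 <- fdr_up
    f2[g, i] <- f2[g, i] / 10
    el1 <- expected_likelihood(panel_from_matrices(f2), mixtures, grid, "up")
    expect_gte(el1[g] + 1e-12, el0[g])
  }
})

test_that("permutation FDR matches the brute-force double loop exactly", {
  set.seed(13)
  for (dims in list(c(20, 3, 5), c(50, 4, 10))) {
    G <- dims[1]; D <- dims[2]; B <- dims[3]
    fdr_up <- matrix(runif(G * D, 0.001, 1.3), G, D,
                     dimnames = list(sprintf("g%03d", 1:G), paste0("d", 1:D)))
    panel <- panel_from_matrices(fdr_up)
    mixtures <- lapply(1:D, function(i) {
      mixture_stub(c(0.05, 0.9, 0.05), G = G)
    })
    grid <- threshold_grid(100)
    res <- permutation_fdr(panel, mixtures, grid, B = B, seed = 31,
                           direction = "up", return_null = TRUE)
    expect_identical(unname(res$fdr_g), oracle_eq4(res$EL, res$null_EL))
  }
})

test_that("degenerate panels produce boundary FDR values", {
  D <- 3; G <- 8
  # identical FDR everywhere: all ELs tie, numerator = denominator scale
  fdr_up <- matrix(0.2, G, D,
                   dimnames = list(sprintf("g%03d", 1:G), paste0("d", 1:D)))
  panel <- panel_from_matrices(fdr_up)
  mixtures <- lapply(1:D, function(i) mixture_stub(c(0.05, 0.9, 0.05), G = G))
  fdr <- permutation_fdr(panel, mixtures, threshold_grid(50), B = 4,
                         seed = 3, direction = "up")
  expect_equal(unname(fdr), rep(1, G))
  # a gene strictly above every null EL gets FDR 0
  fdr_up2 <- fdr_up
  fdr_up2[1, ] <- 1e-4   # uniquely consistent gene
  panel2 <- panel_from_matrices(fdr_up2)
  res2 <- permutation_fdr(panel2, mixtures, threshold_grid(50), B = 4,
                          seed = 3, direction = "up", return_null = TRUE)
  if (all(res2$EL[1] > res2$null_EL)) {
    expect_equal(unname(res2$fdr_g[1]), 0)
  }
  expect_error(permutation_fdr(panel2, mixtures, threshold_grid(50), B = 0,
                               seed = 1, direction = "up"), "B")
})

test_that("null panels are approximately calibrated at the meta level", {
  set.seed(41)
  G <- 1000; D <- 4; B <- 50
  # i.i.d. re-drawn FDR columns: no consistent genes
  fdr_up <- matrix(runif(G * D, 0, 1.5), G, D,
                   dimnames = list(sprintf("g%04d", 1:G), paste0("d", 1:D)))
  panel <- panel_from_matrices(fdr_up)
  mixtures <- lapply(1:D, function(i) mixture_stub(c(0.05, 0.9, 0.05), G = G))
  fdr <- permutation_fdr(panel, mixtures, threshold_grid(100), B = B,
                         seed = 43, direction = "up")
  expect_lte(mean(fdr <= 0.05), 0.05 + 0.02)
})

test_that("the full pipeline flags a planted consistent gene and validates input", {
  set.seed(55)
  G <- 60
  mk <- function(id, seed) {
    set.seed(seed)
    v <- matrix(rnorm(G * 8), G, 8,
                dimnames = list(sprintf("g%03d", 1:G), sprintf("s%d", 1:8)))
    v[1, 1:4] <- v[1, 1:4] + 4            # gene 1 strongly up in cases
    expression_dataset(v, rep(c(1, 0), each = 4), id)
  }
  datasets <- list(mk("a", 56), mk("b", 57))
  res <- suppressWarnings(
    run_cdep(datasets, n_perm = 25, B = 25, seed = 58,
             sampler = list(chains = 2, iter = 500, burnin = 200)))
  expect_equal(names(which.max(res$EL_up)), "g001")
  expect_s3_class(as.data.frame(res), "data.frame")
  expect_error(run_cdep(datasets[1]), "two datasets")
})
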