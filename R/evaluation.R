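#' Score a method's calls against simulation truth
#'
#' Statistical power is the percentage of planted consistently
#' differentially expressed genes (the truth's `gm_genes`) that the method
#' called; the Type I error rate is the fraction of all other genes falsely
#' called. Scoring is direction-agnostic by default (a consistent gene
#' called in the wrong direction still counts as detected); with
#' `strict_direction = TRUE`, `calls` must be a two-column data frame
#' (`gene`, `direction`) and a true positive must match the gene's planted
#' panel-wide direction.
#'
#' @param calls Character vector of called gene identifiers (or a data frame
#'   with columns `gene` and `direction` when `strict_direction = TRUE`).
#' @param truth A `truth_table` from [simulate_panel()].
#' @param threshold The meta-level FDR threshold at which the calls were
#'   made (recorded, not used in the arithmetic).
#' @param method Method label carried into the result.
#' @param strict_direction Require the called direction to match the truth.
#' @return Object of class `evaluation_result` (a one-row data frame) with
#'   `method`, `fdr_threshold`, `power` (percent), `type1`, `n_true_gm`,
#'   `n_called` and `n_false`.
#' @export
score_calls <- function(calls, truth, threshold = NA_real_, method = "",
                        strict_direction = FALSE) {
  stopifnot(inherits(truth, "truth_table"))
  gm <- truth$gm_genes
  if (!length(gm)) stop("truth table has no consistent genes; power undefined")
  if (strict_direction) {
    stopifnot(is.data.frame(calls), all(c("gene", "direction") %in% names(calls)))
    planted_dir <- apply(truth$direction[gm, , drop = FALSE], 1L, function(r) {
      d <- unique(r[!is.na(r) & r != "none"]); if (length(d) == 1L) d else NA
    })
    called_gm <- calls$gene %in% gm
    ok <- calls$direction[called_gm] ==
      planted_dir[match(calls$gene[called_gm], gm)]
    tp <- sum(ok, na.rm = TRUE)
    called <- unique(calls$gene)
  } else {
    called <- unique(as.character(calls))
    tp <- sum(called %in% gm)
  }
  n_called <- length(called)
  fp <- sum(!called %in% gm)
  n_nongm <- length(truth$genes) - length(gm)
  out <- data.frame(method = method, fdr_threshold = threshold,
                    power = 100 * tp / length(gm), type1 = fp / n_nongm,
                    n_true_gm = length(gm), n_called = n_called,
                    n_false = fp)
  class(out) <- c("evaluation_result", class(out))
  out
}

## Run all three methods on one simulated panel and score them.
## Shares the rank-product stage between the main method and the
## signature-count comparator.
run_methods_on_panel <- function(panel_sim, fdr_call = 0.05, n_perm = 50L,
                                 B = 50L, seed = NULL,
                                 sampler = list(chains = 2L, iter = 1200L,
                                                burnin = 400L),
                                 methods = c("cdep", "meta_profile",
                                             "meta_rankprod"),
                                 signature_l = 0.05) {
  datasets <- panel_sim$datasets
  truth <- panel_sim$truth
  rows <- list()
  res <- run_cdep(datasets, n_perm = n_perm, B = B, fdr_call = fdr_call,
                  seed = derive_seed(seed, 1L), sampler = sampler)
  if ("cdep" %in% methods) {
    rows$cdep <- score_calls(called_genes(res), truth, fdr_call, "cdep")
  }
  if ("meta_profile" %in% methods) {
    mp_up <- meta_profile(res$panel, l = signature_l, B = B,
                          seed = derive_seed(seed, 11L), direction = "up",
                          fdr_call = fdr_call)
    mp_down <- meta_profile(res$panel, l = signature_l, B = B,
                            seed = derive_seed(seed, 12L),
                            direction = "down", fdr_call = fdr_call)
    called <- union(mp_up$genes[mp_up$call != "none"],
                    mp_down$genes[mp_down$call != "none"])
    rows$meta_profile <- score_calls(called, truth, fdr_call, "meta_profile")
  }
  if ("meta_rankprod" %in% methods) {
    mr <- meta_rankprod(datasets, res$universe, B = B,
                        seed = derive_seed(seed, 21L), direction = "both",
                        fdr_call = fdr_call)
    called <- union(mr$up$genes[mr$up$call != "none"],
                    mr$down$genes[mr$down$call != "none"])
    rows$meta_rankprod <- score_calls(called, truth, fdr_call,
                                      "meta_rankprod")
  }
  do.call(rbind, rows)
}

#' Power / Type-I-error comparison grid over simulation scenarios
#'
#' For each scenario (a combination of the dataset-specific proportion p,
#' consistent proportion q, effect size delta and meta-level call FDR), this
#' simulates `replicates` independent panels, runs the requested methods on
#' each, and scores power and Type I error against the planted truth. All
#' methods see the same simulated panels within a replicate.
#'
#' @param scenarios Data frame with columns `p`, `q`, `delta`, `fdr`.
#' @param replicates Number of simulation replicates per scenario.
#' @param seed Master seed; replicate panels and method permutation streams
#'   are derived from it, so the same seed reproduces the grid exactly.
#' @param shapes A [simulation_config()] giving the panel shapes and
#'   nuisance parameters; its `p`, `q`, `delta` are overridden per scenario.
#' @param methods Character subset of
#'   `c("cdep", "meta_profile", "meta_rankprod")`.
#' @param n_perm,B,sampler Pipeline settings, see [run_cdep()].
#' @return Data frame with one row per scenario x method x replicate;
#'   aggregate with [grid_means()].
#' @export
table1_grid <- function(scenarios, replicates = 10L, seed = 1L,
                        shapes = default_table2_shapes(genes = 2000L),
                        methods = c("cdep", "meta_profile", "meta_rankprod"),
                        n_perm = 50L, B = 50L,
                        sampler = list(chains = 2L, iter = 1200L,
                                       burnin = 400L)) {
  stopifnot(is.data.frame(scenarios),
            all(c("p", "q", "delta", "fdr") %in% names(scenarios)))
  out <- list()
  ## scenarios sharing (p, q, delta) reuse the same simulated panels, so
  ## call-threshold comparisons are paired
  sim_key <- match(paste(scenarios$p, scenarios$q, scenarios$delta),
                   unique(paste(scenarios$p, scenarios$q, scenarios$delta)))
  for (s in seq_len(nrow(scenarios))) {
    sc <- scenarios[s, ]
    cfg <- simulation_config(m = shapes$m, n = shapes$n, G = shapes$G,
                             p = sc$p, q = sc$q, delta = sc$delta,
                             psi = shapes$psi, mu = shapes$mu,
                             lab_sd = shapes$lab_sd,
                             gene_sd = shapes$gene_sd,
                             noise_sd = shapes$noise_sd)
    for (rep_i in seq_len(replicates)) {
      sim_seed <- derive_seed(seed, 10000L * sim_key[s] + rep_i)
      panel_sim <- simulate_panel(cfg, seed = sim_seed)
      scored <- run_methods_on_panel(
        panel_sim, fdr_call = sc$fdr, n_perm = n_perm, B = B,
        seed = derive_seed(seed, 10000L * sim_key[s] + 1000L + rep_i),
        methods = methods)
      scored$p <- sc$p; scored$q <- sc$q; scored$delta <- sc$delta
      scored$fdr <- sc$fdr; scored$replicate <- rep_i
      out[[length(out) + 1L]] <- scored
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mean power and Type I error per scenario and method
#'
#' @param grid A [table1_grid()] result.
#' @return Data frame of replicate means (and standard deviations) per
#'   scenario x method.
#' @export
grid_means <- function(grid) {
  key <- interaction(grid$p, grid$q, grid$delta, grid$fdr, grid$method,
                     drop = TRUE)
  agg <- lapply(split(grid, key), function(d) {
    data.frame(p = d$p[1L], q = d$q[1L], delta = d$delta[1L],
               fdr = d$fdr[1L], method = d$method[1L],
               power = mean(d$power), power_sd = sd(d$power),
               type1 = mean(d$type1), type1_sd = sd(d$type1),
               replicates = nrow(d))
  })
  res <- do.call(rbind, agg)
  rownames(res) <- NULL
  res[order(res$p, res$q, res$delta, res$fdr, res$method), ]
}
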