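#' Configuration for the multi-dataset expression simulator
#'
#' Describes a panel of D two-condition datasets generated from the additive
#' model
#' `y = mu + L_i + G_gi + alpha_g * T + beta_g * M + eps`,
#' where `mu` is the universal background, `L_i ~ N(0, lab_sd^2)` a
#' laboratory effect, `G_gi ~ N(0, gene_sd^2)` a per-gene per-dataset
#' baseline, and `eps ~ N(0, noise_sd^2)` measurement noise. Case samples of
#' genes planted as differentially expressed additionally receive an effect
#' drawn per sample from `N(sign * delta, psi)` (psi is a variance): for
#' dataset-specific genes (`alpha_g = 1`, frequency p) the sign is drawn per
#' (gene, dataset); for consistent genes (`beta_g = 1`, frequency q) the
#' sign is drawn once per gene and shared by all datasets. A gene belongs to
#' at most one category: alpha is drawn first with rate p, and beta with
#' rate q/(1 - p) among the remaining genes, so the marginal rates are p
#' and q.
#'
#' @param m,n Integer vectors of case / control sample counts per dataset.
#' @param G Integer vector of per-dataset gene counts; platforms are nested,
#'   so dataset i carries the first `G[i]` genes of the largest platform.
#' @param p Proportion of dataset-specific differentially expressed genes.
#' @param q Proportion of consistently differentially expressed genes.
#' @param delta Absolute effect-size mean (must be nonzero).
#' @param psi Effect variance around delta.
#' @param mu Universal background level (log2 scale).
#' @param lab_sd,gene_sd,noise_sd Standard deviations of the laboratory,
#'   per-gene baseline and noise terms (`gene_sd`, `noise_sd` recycled per
#'   dataset).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(m, n, G, p = 0.05, q = 0.05, delta = 1,
                              psi = 0.25, mu = 8, lab_sd = 0.5,
                              gene_sd = 1, noise_sd = 0.5) {
  D <- length(m)
  stopifnot(D >= 1L, length(n) == D, length(G) == D,
            all(m >= 1L), all(n >= 1L), all(G >= 2L))
  if (p < 0 || q < 0 || p + q > 1) stop("need p >= 0, q >= 0 and p + q <= 1")
  if (delta == 0) stop("'delta' must be nonzero")
  if (psi <= 0 || lab_sd <= 0 || any(gene_sd <= 0) || any(noise_sd <= 0)) {
    stop("variance parameters must be positive")
  }
  structure(
    list(D = D, m = as.integer(m), n = as.integer(n), G = as.integer(G),
         p = p, q = q, delta = abs(delta), psi = psi, mu = mu,
         lab_sd = lab_sd, gene_sd = rep_len(gene_sd, D),
         noise_sd = rep_len(noise_sd, D)),
    class = "simulation_config")
}

#' Panel shapes mimicking six metastatic-vs-primary cancer studies
#'
#' Returns a [simulation_config()] whose sample sizes (metastatic cases /
#' primary controls) and relative gene counts follow six published cancer
#' expression studies of different platforms: cervical (12/21, 20,271
#' genes), prostate (25/65, 9,000), gastric (15/7, 5,526), colon (3/3,
#' 13,069), oral squamous cell (19/8, 13,069) and renal cell (10/22,
#' 13,069). Smaller platforms are treated as nested subsets of the largest.
#'
#' @param genes Optionally rescale the gene counts so the largest platform
#'   has this many genes (proportions preserved); `NULL` keeps the original
#'   counts.
#' @param ... Further arguments (`p`, `q`, `delta`, ...) passed to
#'   [simulation_config()].
#' @return A `simulation_config` with D = 6.
#' @export
default_table2_shapes <- function(genes = NULL, ...) {
  m <- c(12L, 25L, 15L, 3L, 19L, 10L)
  n <- c(21L, 65L, 7L, 3L, 8L, 22L)
  G <- c(20271L, 9000L, 5526L, 13069L, 13069L, 13069L)
  if (!is.null(genes)) G <- pmax(2L, as.integer(round(G * genes / max(G))))
  simulation_config(m = m, n = n, G = G, ...)
}

#' Simulate a multi-dataset expression panel with planted effects
#'
#' Draws a panel of two-condition datasets from the model described in
#' [simulation_config()], along with the ground truth needed for power and
#' Type-I-error evaluation. Sample columns are ordered cases first; gene
#' identifiers are shared across datasets (nested platforms).
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed (optional).
#' @return List with `datasets` (list of [expression_dataset()]) and `truth`
#'   (class `truth_table`): per-gene category (`"M"` consistent, `"C"`
#'   dataset-specific, `"N"` null), per-(gene, dataset) direction matrix
#'   (`"up"` / `"down"` / `"none"`, `NA` where absent), and the consistent
#'   gene set `gm_genes`.
#' @export
simulate_panel <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  G_max <- max(cfg$G)
  genes <- sprintf("g%05d", seq_len(G_max))
  with_seed(seed, {
    alpha <- rbinom(G_max, 1L, cfg$p) == 1L
    beta <- rep(FALSE, G_max)
    if (cfg$p < 1) {
      beta[!alpha] <- rbinom(sum(!alpha), 1L, cfg$q / (1 - cfg$p)) == 1L
    }
    dir_m <- sample(c(1, -1), G_max, replace = TRUE)     # panel-wide sign
    category <- ifelse(beta, "M", ifelse(alpha, "C", "N"))
    direction <- matrix(NA_character_, G_max, cfg$D,
                        dimnames = list(genes, paste0("sim", seq_len(cfg$D))))
    datasets <- vector("list", cfg$D)
    for (i in seq_len(cfg$D)) {
      Gi <- cfg$G[i]
      idx <- seq_len(Gi)
      mi <- cfg$m[i]; ni <- cfg$n[i]
      S <- mi + ni
      L_i <- rnorm(1L, 0, cfg$lab_sd)
      G_gi <- rnorm(Gi, 0, cfg$gene_sd[i])
      vals <- matrix(rnorm(Gi * S, 0, cfg$noise_sd[i]), Gi, S)
      vals <- vals + cfg$mu + L_i + G_gi
      dir_c <- sample(c(1, -1), Gi, replace = TRUE)      # per-dataset sign
      sign_i <- ifelse(beta[idx], dir_m[idx], dir_c)
      de <- alpha[idx] | beta[idx]
      if (any(de)) {
        eff <- matrix(rnorm(sum(de) * mi, mean = rep(sign_i[de] * cfg$delta, mi),
                            sd = sqrt(cfg$psi)), sum(de), mi)
        vals[de, seq_len(mi)] <- vals[de, seq_len(mi)] + eff
      }
      dimnames(vals) <- list(genes[idx],
                             sprintf("s%03d", seq_len(S)))
      direction[idx, i] <- ifelse(de, ifelse(sign_i > 0, "up", "down"),
                                  "none")
      datasets[[i]] <- expression_dataset(
        vals, condition = rep(c(1L, 0L), c(mi, ni)),
        dataset_id = paste0("sim", i))
    }
    truth <- structure(
      list(genes = genes, category = setNames(category, genes),
           direction = direction, gm_genes = genes[beta],
           gc_genes = genes[alpha]),
      class = "truth_table")
    list(datasets = datasets, truth = truth)
  })
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf(
    "truth_table: %d genes (%d consistent, %d dataset-specific, %d null)\n",
    length(x$genes), sum(x$category == "M"), sum(x$category == "C"),
    sum(x$category == "N")))
  invisible(x)
}

#' Write a simulated panel to tab-delimited files
#'
#' One matrix and one label file per dataset, plus a truth table TSV.
#'
#' @param panel A [simulate_panel()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ds in panel$datasets) {
    mat <- data.frame(gene = ds$genes, ds$values, check.names = FALSE)
    write.table(mat, file.path(dir, paste0(ds$dataset_id, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(sample = ds$samples, condition = ds$condition),
                file.path(dir, paste0(ds$dataset_id, "_labels.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  tt <- panel$truth
  write.table(
    data.frame(gene = tt$genes, category = unname(tt$category),
               tt$direction, check.names = FALSE),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
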