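#' Construct a two-condition expression dataset
#'
#' Bundles one study's log-scale expression matrix (genes in rows, samples in
#' columns) with a binary condition label per sample (1 = case, e.g.
#' metastatic; 0 = control, e.g. primary).
#'
#' @param values Numeric matrix, genes x samples, log-scale expression with
#'   row names (gene or probeset identifiers) and column names (sample
#'   identifiers). Missing values are rejected.
#' @param condition Integer/numeric vector of 0/1 labels, either in column
#'   order or named by sample identifier.
#' @param dataset_id Short identifier for the study.
#' @param log2_transform If `TRUE`, values are log2(x + 1) transformed on
#'   entry (for raw-scale input); by default values are assumed to be on the
#'   log scale already.
#' @return An object of class `expression_dataset` with elements `dataset_id`,
#'   `genes`, `samples`, `values`, `condition`, `m` (number of cases) and `n`
#'   (number of controls).
#' @export
expression_dataset <- function(values, condition, dataset_id = "dataset",
                               log2_transform = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values))) stop("'values' must have gene row names")
  if (is.null(colnames(values))) stop("'values' must have sample column names")
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene identifiers in dataset '", dataset_id, "'")
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample identifiers in dataset '", dataset_id, "'")
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop("missing value at gene '", rownames(values)[bad[1L]],
         "', sample '", colnames(values)[bad[2L]], "'")
  }
  if (!is.null(names(condition))) {
    missing_lab <- setdiff(colnames(values), names(condition))
    if (length(missing_lab)) {
      stop("no condition label for sample(s): ",
           paste(missing_lab, collapse = ", "))
    }
    condition <- condition[colnames(values)]
  }
  if (length(condition) != ncol(values)) {
    stop("'condition' must have one label per sample column")
  }
  condition <- as.integer(condition)
  if (!all(condition %in% c(0L, 1L))) stop("condition labels must be 0 or 1")
  m <- sum(condition == 1L)
  n <- sum(condition == 0L)
  if (m < 1L || n < 1L) stop("need at least one case and one control sample")
  if (log2_transform) values <- log2(values + 1)
  structure(
    list(dataset_id = as.character(dataset_id),
         genes = rownames(values), samples = colnames(values),
         values = values, condition = condition, m = m, n = n),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset '%s': %d genes, %d cases + %d controls\n",
              x$dataset_id, length(x$genes), x$m, x$n))
  invisible(x)
}

#' Read an expression matrix and its sample labels
#'
#' Reads a tab-delimited expression matrix (first column gene/probeset
#' identifier, header row of sample identifiers) or a GCT 1.2 file (version
#' and dimension lines skipped, `Description` column dropped), together with a
#' two-column label file mapping `sample<TAB>condition` with condition in
#' \{0, 1\}.
#'
#' @inheritParams expression_dataset
#' @param path Path to the matrix file (`.tsv` or `.gct`).
#' @param label_path Path to the label file.
#' @return An [expression_dataset()].
#' @export
read_expression_matrix <- function(path, label_path, dataset_id = NULL,
                                   log2_transform = FALSE) {
  if (is.null(dataset_id)) {
    dataset_id <- sub("\\.[^.]*$", "", basename(path))
  }
  first <- readLines(path, n = 1L)
  is_gct <- startsWith(first, "#1.2")
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character",
                    skip = if (is_gct) 2L else 0L)
  if (ncol(tab) < 2L) stop("matrix file must have at least one sample column")
  ids <- tab[[1L]]
  tab <- tab[, -1L, drop = FALSE]
  if (is_gct && tolower(names(tab)[1L]) == "description") {
    tab <- tab[, -1L, drop = FALSE]
  }
  if (anyDuplicated(names(tab))) {
    stop("duplicate sample identifiers in '", path, "'")
  }
  vals <- matrix(NA_real_, nrow = nrow(tab), ncol = ncol(tab),
                 dimnames = list(ids, names(tab)))
  for (j in seq_len(ncol(tab))) {
    v <- suppressWarnings(as.numeric(tab[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop("non-numeric value '", tab[[j]][i], "' at row '", ids[i],
           "', column '", names(tab)[j], "' in '", path, "'")
    }
    vals[, j] <- v
  }
  lab <- read.delim(label_path, header = FALSE, sep = "\t",
                    colClasses = "character")
  if (ncol(lab) < 2L) stop("label file must have two columns")
  if (nrow(lab) && !lab[1L, 2L] %in% c("0", "1")) lab <- lab[-1L, , drop = FALSE]
  condition <- suppressWarnings(as.integer(lab[[2L]]))
  names(condition) <- lab[[1L]]
  expression_dataset(vals, condition, dataset_id = dataset_id,
                     log2_transform = log2_transform)
}

#' Collapse probeset rows to gene level by the per-sample median
#'
#' Probesets mapping to the same gene are summarised by their median
#' expression value, computed sample by sample. Probesets absent from the
#' mapping, or mapping to more than one gene, are dropped (with a message).
#'
#' @param ds An [expression_dataset()] whose rows are probesets.
#' @param mapping Two-column data frame (`probeset`, `gene`).
#' @return An [expression_dataset()] with one row per gene.
#' @export
collapse_probesets <- function(ds, mapping) {
  stopifnot(inherits(ds, "expression_dataset"))
  mapping <- data.frame(probeset = as.character(mapping[[1L]]),
                        gene = as.character(mapping[[2L]]))
  multi <- unique(mapping$probeset[duplicated(mapping$probeset)])
  if (length(multi)) {
    message(length(multi), " probeset(s) mapping to multiple genes dropped")
    mapping <- mapping[!mapping$probeset %in% multi, , drop = FALSE]
  }
  mapping <- mapping[mapping$probeset %in% ds$genes, , drop = FALSE]
  if (!nrow(mapping)) stop("no probeset in the mapping matches the dataset")
  unmapped <- setdiff(ds$genes, mapping$probeset)
  if (length(unmapped)) {
    message(length(unmapped), " unmapped probeset(s) dropped")
  }
  idx <- split(match(mapping$probeset, ds$genes), mapping$gene)
  genes <- names(idx)
  vals <- matrix(NA_real_, nrow = length(genes), ncol = ncol(ds$values),
                 dimnames = list(genes, ds$samples))
  for (g in seq_along(idx)) {
    rows <- ds$values[idx[[g]], , drop = FALSE]
    vals[g, ] <- apply(rows, 2L, median)
  }
  expression_dataset(vals, ds$condition, dataset_id = ds$dataset_id)
}

#' Assemble the cross-dataset gene universe
#'
#' The union of gene identifiers across all datasets, in deterministic
#' (lexicographic, C-locale) order, with a gene-by-dataset presence matrix.
#'
#' @param datasets List of [expression_dataset()] objects (at least two).
#' @return Object of class `gene_universe` with `genes` and logical matrix
#'   `membership` (genes x datasets).
#' @export
build_universe <- function(datasets) {
  stopifnot(length(datasets) >= 2L)
  ids <- vapply(datasets, function(d) d$dataset_id, character(1L))
  if (anyDuplicated(ids)) stop("dataset identifiers must be unique")
  genes <- sort(unique(unlist(lapply(datasets, `[[`, "genes"))),
                method = "radix")
  membership <- vapply(datasets, function(d) genes %in% d$genes,
                       logical(length(genes)))
  dimnames(membership) <- list(genes, ids)
  structure(list(genes = genes, membership = membership),
            class = "gene_universe")
}

#' @export
print.gene_universe <- function(x, ...) {
  cat(sprintf("gene_universe: %d genes across %d datasets (%d shared by all)\n",
              length(x$genes), ncol(x$membership),
              sum(rowSums(x$membership) == ncol(x$membership))))
  invisible(x)
}
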