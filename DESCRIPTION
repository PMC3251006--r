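Package: cdep
Title: Consistent Differential Expression Patterns Across Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Meta-analysis of two-condition gene expression studies to find
    genes that are consistently up- or down-regulated across heterogeneous
    datasets. Per-dataset evidence comes from the non-parametric rank product
    with permutation p-values and rank-based false discovery rates; a
    three-component Beta mixture fitted to each dataset's one-sided p-values
    estimates the number of non-regulated genes; per-dataset false-positive
    rates are then combined through a Bernoulli likelihood integrated over a
    density of FDR thresholds, and gene-level significance is assessed by a
    permutation FDR. Includes two comparator meta-analysis methods
    (signature counting and a pooled cross-dataset rank product), a
    multi-dataset expression simulator with planted consistent and
    dataset-specific effects, and power / Type-I-error evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
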