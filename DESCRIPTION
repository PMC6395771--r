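Package: modpres
Title: Case-Control Differential Expression and Coexpression Module
    Preservation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for small case-control bulk RNA-seq
    cohorts: CPM-based expression filtering, size-factor normalized log
    expression, residual-SVD surrogate variable estimation, per-sample
    quality weights, negative-binomial Wald differential expression with
    covariates, weighted gene coexpression networks (soft threshold,
    topological overlap, module detection, eigengenes, kME), reference-based
    permutation module preservation (Zsummary, medianRank) with a
    kME-correlation tie-break for selecting the least preserved module,
    hub-gene conservation, and gene-set enrichment (hypergeometric
    over-representation and randomization tests). Includes a synthetic-data
    generator with planted coexpression modules, a disrupted module,
    differentially expressed genes and batch structure, used for calibration
    and recovery benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
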