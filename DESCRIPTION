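Package: aspen
Title: Age-Specific Program Enrichment for Annotated Single-Cell Transcriptomics
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Cell-type-resolved discovery of age-related gene programs in
    annotated single-cell expression cohorts. A dual-arm enrichment framework
    combines correlation-ranked permutation GSEA with a parametric gene set
    test (dual Benjamini-Hochberg gate) and binned-control signature scoring
    correlated with donor age. Companion procedures cover age trends in
    cell-type composition, regression-based prioritization of ligand-receptor
    signaling nodes from cell-cell communication tables, and fixed-radius
    spatial proximity analysis of multiplexed-imaging cell tables. Includes
    seeded synthetic-cohort generators with ground-truth ledgers so every
    stage can be exercised and power-tested without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
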