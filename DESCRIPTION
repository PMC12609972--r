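Package: arrayz
Title: Two-Color Microarray Analysis with Intensity-Dependent Z-Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, simulation-backed pipeline for spot-level
    two-color cDNA microarray experiments: background correction, quality
    filtering, MA-plot LOWESS dye-bias normalization, replicate averaging,
    and differential-expression calling by an intensity-dependent
    sliding-window Z-score. Downstream stages cover literature-set
    concordance classification, hypergeometric over-representation analysis
    with Benjamini-Hochberg tiers and term-overlap networks, confidence-
    filtered protein-protein interaction hub detection, and gene-signature
    median-split survival with Spearman infiltration correlation. A
    synthetic-data generator with planted ground truth (dye bias, true fold
    changes, enriched terms, network hubs, hazard ratios, rank
    correlations) makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
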