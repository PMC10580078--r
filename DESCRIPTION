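Package: wormspan
Title: Lifespan Assay Analysis and Editable Survival Plots for C. elegans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing manually scored lifespan assays of
    Caenorhabditis elegans and similar survival experiments. Reads daily
    scoring sheets of alive/dead/censored counts (CSV or Excel), flattens
    them to per-individual right-censored event tables, fits Kaplan-Meier
    survival curves, compares each condition to a designated control with
    Gehan's censoring-aware generalized Wilcoxon rank-sum test (with an
    exact permutation option), and renders annotated, hand-editable SVG
    survival plots with auto-generated titles, legends (mean lifespan, n,
    p-values, significance stars, italicized gene names) and captions.
    Supports batch processing of directories of experiments, a seeded
    synthetic-experiment generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    readxl,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
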