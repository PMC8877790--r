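Package: larvatox
Title: Developmental Toxicity Screening Analysis for Larval Zebrafish
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical workflow for larval zebrafish developmental
    toxicity studies of endocrine-disrupting chemicals: quality control of
    larval photomotor response traces (per-trace IQR serial-exceedance,
    dark-below-light-median and light:dark ratio rules), behavioral group
    comparisons (one-way ANOVA with Tukey HSD), morphology and mortality
    endpoint screening (chi-square with Bonferroni-corrected pairwise
    comparisons and a 100 percent mortality evaluability gate),
    differential-expression threshold filtering with count and set-overlap
    accounting, and molar-to-mass concentration conversion. A seeded
    synthetic-data generator emulates the three input kinds (locomotion
    traces, screening count tables, per-gene DE results) with known ground
    truth so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
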