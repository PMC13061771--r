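Package: epichron
Title: Leukocyte Transcriptome Correlates of Epilepsy Duration and Onset Age
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for relating bulk leukocyte RNA-seq
    expression to the clinical course of epilepsy. Provides expression
    filtering on counts-per-million (CPM) with a dataset-derived pseudocount
    and log2 transformation, cohort stratification by epilepsy duration or
    age at seizure onset with descriptive statistics and tie- and
    continuity-corrected Mann-Whitney group comparisons, Welch t or rank-sum
    differential expression with volcano-style classification, Spearman
    trait-correlation screening with exclusion of age-associated genes,
    covariate-adjusted partial Spearman correlation via double
    residualization, directional gene-list overlap, hypergeometric
    over-representation analysis on cytogenetic bands, and a synthetic
    cohort and expression generator with ground-truth bookkeeping for
    recovery testing.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
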