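Package: seropanel
Title: Autoantibody Screening and Diagnostic Panel Selection for
    Multiplex Bead-Array Serology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multiplex bead-array (Luminex-type)
    autoantibody data in Sjogren's disease serology studies: log2
    transformation and sample-wise median centering, low-reactivity
    pre-filtering, univariate candidate screening (Mann-Whitney, SAM
    d-statistic with permutation significance, fold change, quantile
    span), healthy-control-anchored binarization with 98%-quantile
    cutoffs and data-driven cutoff escalation, prevalence and
    co-prevalence estimation, greedy forward selection of OR-rule
    diagnostic marker panels for Ro/SSA-negative patients, logistic
    screening of clinical-manifestation associations with
    Benjamini-Hochberg adjustment, ELISA standard-curve quantification,
    and a synthetic-cohort generator with a ground-truth ledger for
    recovery and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
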