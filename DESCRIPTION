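Package: autoicd
Title: Rule-Based Preprocessing and Multilabel Classification for Automatic ICD-10 Coding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building automatic ICD-10-CM and ICD-10-PCS coding
    pipelines from hospital discharge summaries. Implements rule-based
    clinical-text preprocessing (punctuation and non-Latin character removal,
    essential-number conversion to words, medical-history and
    special-examination keyword extraction, combination-code filtering,
    external-cause label removal, definition pretraining pairs), a pluggable
    multilabel text classifier with a deterministic bag-of-words linear
    backend, micro-averaged evaluation metrics with document-level bootstrap
    confidence intervals, an ablation harness over preprocessing
    configurations and section-combination strategies, and a seeded synthetic
    discharge-summary generator with ground-truth mechanism manifests so
    every pipeline stage is testable without access to protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
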