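Package: fcdecoder
Title: Decoding Stimulus Categories from Whole-Brain Functional Connectivity Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multivariate pattern analysis of ROI-to-ROI
    functional connectivity in block-design fMRI: CompCor-style nuisance
    regression and band-pass filtering of ROI time series, condition-specific
    Fisher-z connectivity matrices, group-level edge statistics with
    Benjamini-Hochberg FDR control, and six-way decoding of stimulus
    categories from pooled positive-connectivity edges using
    leave-one-subject-out cross-validation, fold-internal ANOVA feature
    selection, a one-vs-one linear support-vector ensemble, and
    permutation-based significance. Includes a synthetic cohort generator
    with planted edge-level class effects so every stage is testable without
    any imaging data, plus behavioral-response summaries and paired tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
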