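Package: irscore
Title: Recurrence Risk Scoring from Infrared Spectroscopic Tissue Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts post-prostatectomy biochemical recurrence from
    FT-IR spectroscopic imaging of tumor-adjacent tissue. Per-pixel infrared
    spectra are reduced to spectral metrics, discretized, and mined for
    frequent co-occurrence patterns (FP-growth); class-discriminative patterns
    become per-core frequency features for a pairwise Ranking-SVM. Rank
    preferences between a patient's cores and matched reference patients are
    normalized and converted to a probability of recurrence (the IR Score)
    by logistic regression. Includes a matched case-control synthetic cohort
    generator with planted pattern signal, a CAPRA-S baseline scorer with a
    pluggable nomogram interface, and the evaluation machinery used in this
    setting: nested pair cross-validation with exact binomial tests, query
    cross-validation, empirical and binormal-smoothed ROC/AUC with bootstrap
    confidence intervals, Kolmogorov-Smirnov score comparisons, and quartile
    odds ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
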