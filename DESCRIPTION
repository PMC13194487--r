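Package: goldstage
Title: Ordinal Neural Networks for COPD GOLD Stage Prediction from
    Heterogeneous Clinical Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts COPD severity (GOLD stages 1-4) from tabular clinical
    cohorts whose feature sets only partially overlap. Implements a
    shared-private ordinal neural network: a common encoder for features
    present in every cohort, cohort-specific private encoders for the rest,
    and a cumulative-threshold ordinal head trained with per-threshold
    binary cross-entropy. Missing measurements are represented by value-mask
    encoding instead of imputation, so a true zero stays distinguishable
    from an absent value. Ships ordinal evaluation metrics (stage MAE,
    quadratic weighted kappa, within-one-stage error rate), a stratified
    splitter, multiclass and logistic-regression baselines, two encoder
    ablations, an experiment-suite runner, and a synthetic paired-cohort
    generator so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
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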