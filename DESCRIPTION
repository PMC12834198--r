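Package: feddistill
Title: Federated Soft-Label Distillation with a Permissioned Trust Ledger
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, seedable simulator of federated ensemble
    learning over heterogeneous clinical participants. Local models of
    different families (random forest, k-nearest neighbours, gradient
    boosted trees, decision tree, linear support-vector machine) exchange
    temperature-scaled class-probability vectors (soft labels) instead of
    data or parameters; an aggregator combines them by accuracy-weighted
    soft voting with weight clipping, filters the consensus by a
    confidence threshold, and feeds the surviving pseudo-labels back into
    local training. An in-process role-based-access-control ledger
    validates every submission (identity, role, round, timestamp,
    declared-accuracy consistency) with SHA-256 payload hashing and
    multi-validator quorum approval, and produces transaction-integrity
    audits. Includes a synthetic diabetes-cohort generator with
    controllable prevalence, signal strength and non-IID label skew, the
    stated preprocessing chain (IQR and local-outlier-factor screening,
    clinical binning, z-scoring, SMOTE balancing), and percentile
    bootstrap comparison of classifier predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    digest,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
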