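Package: connpredict
Title: Individualized Prediction of Behaviour from Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Connectome-based individualized prediction of a behavioural
    score (modelled on the Pittsburgh Sleep Quality Index) from whole-brain
    nodal functional-connectivity strength. Implements a from-scratch
    relevance vector regression engine (sparse Bayesian linear-kernel
    regression with type-II maximum-likelihood hyperparameter updates),
    leakage-safe leave-one-out and repeated k-fold cross-validation with
    per-fold min-max feature scaling, permutation significance of
    prediction accuracy, contribution-weight region ranking with a
    second-stage edge-level model, network-pair weight aggregation, and
    supporting statistics (covariate-controlled partial correlation and
    Benjamini-Hochberg screening). A synthetic-cohort generator with
    planted connectome-to-score signal provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
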