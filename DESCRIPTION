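Package: mskSurrogate
Title: Machine-Learning Surrogates for Posture-Dependent Musculoskeletal
    Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for approximating posture-dependent musculoskeletal
    kinematics (musculotendon lengths and joint moment arms as functions of
    joint angles) with machine-learning surrogate models. Provides a
    generator of polynomial reference models of the human arm and hand in
    which moment arms are analytic partial derivatives of muscle length,
    uniform posture sampling with a fixed train/validation/test protocol,
    per-channel gradient-boosted regression-tree surrogates with Bayesian
    hyperparameter tuning and early stopping, fully connected neural-network
    surrogates trained with a worst-percentile cost and a plateau learning
    rate schedule, and range- and maximum-normalized error metrics with
    distribution summaries, extreme-posture tests, dataset-size sweeps and
    latency benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    lhs,
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
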