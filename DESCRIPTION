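Package: stepcut
Title: Bayesian Step-Function Cutoff Estimation for Clinical Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates an optimal biomarker cutoff that separates subjects at
    low versus high risk of a binary clinical outcome, using a Bayesian
    step-function (change-point) Bernoulli model with a robust weighted-sum
    prior on the cutoff and Metropolis-within-Gibbs sampling. Developed for
    thyrotropin (TSH) thresholds predicting preterm birth in pregnancy
    cohorts, but applicable to any positive continuous marker and binary
    outcome. Also provides the frequentist comparators used in that setting
    (empirical ROC/AUC, Youden index, predictive summary index, bootstrap
    confidence intervals), split-sample validation with cross-validated AUC
    of a Bayesian logistic model on the dichotomized marker, Gelman-Rubin
    convergence diagnostics, a prior-predictive importance-sampling oracle
    for posterior checking, and a synthetic cohort generator that emulates
    the statistical structure of a pregnancy thyroid-screening study.
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
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    coda,
    foreign,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
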