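Package: itepredict
Title: Individualized Treatment Effect Prediction from Randomized Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts individualized treatment effects (absolute risk
    differences between two randomized treatment arms with a binary
    endpoint) from logistic regression models with treatment-covariate
    interactions, estimated by maximum likelihood or penalized maximum
    likelihood (ridge, lasso, and a hierarchical group lasso that
    enforces strong hierarchy between main effects and interactions).
    Includes a parametric randomized-trial simulator with known
    potential-outcome risks, risk-modeling and significance-based
    comparator models, performance measures on the risk-difference scale
    (root mean squared prediction error, quantile absolute errors,
    calibration tables), bootstrap internal validation with out-of-bag
    Brier score and Nagelkerke R-squared, treatment-effect calibration by
    quantile groups, and a factorial simulation-study runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ggplot2,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
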