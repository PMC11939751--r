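Package: brsurvey
Title: Bayesian Rule Set Analysis of Ordinal Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for interpretable OR-of-ANDs rule set
    classification of survey data. Implements overlapping incremental
    binarization of ordinal and continuous survey variables, candidate rule
    mining with minimum support, Bayesian rule set inference with a Poisson
    prior on rule-set size and a Beta-Binomial classification likelihood
    searched by annealed multi-chain MCMC, bootstrap prevalence/coverage
    stability analysis, a propensity-score and mediation extension that
    treats fitted rules as regression indicators, and LASSO/decision-tree/
    random-forest baselines. Ships a synthetic survey generator with
    planted rule structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    rpart,
    randomForest,
    car
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
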