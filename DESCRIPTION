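Package: prosolearn
Title: Simulation and Model-Based Analysis of Prosocial Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying value-based learning when outcomes benefit
    oneself, an unknown other, or no one. Implements a seeded simulator of a
    two-choice probabilistic reward task with three beneficiary conditions,
    Rescorla-Wagner learning with a softmax choice rule (one learning rate, or
    separate gain/loss rates), maximum a posteriori fitting with weakly
    informative priors, BIC model comparison, parameter-recovery pipelines, an
    age-structured synthetic cohort generator, behavioral summaries (learning
    curves, above-chance tests, partial Spearman correlations), and export of
    trial-wise expected-value and prediction-error regressors as BIDS-style
    event files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
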