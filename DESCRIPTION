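Package: errmeta
Title: Bayesian Meta-Analysis of Measurement-Error Bias and Variability
    from Published Aggregates
Version: 0.1.0
Authors@R:
    person("CEDIT", "Methods", email = "methods@example.org",
           role = c("aut", "cre"))
Description: Pools published per-series aggregates (sample size, mean error,
    SD of error) of a measurement method by Bayesian hierarchical
    meta-analysis, estimating both the bias and the variability of the
    method under exact normal-sampling likelihoods (Student-t for the
    observed mean, scaled chi-square for the observed SD).  A joint model
    quantifies the effect of an initial per-patient calibration through a
    bias-correction term and a SD-ratio constrained to (0, sqrt(2)).
    Posterior-predictive replication draws for a new study and a new
    observation are converted into clinical decision-error probabilities
    (sensitivity, specificity, predictive values, probability of a false
    report) at user-chosen thresholds, assuming a uniform distribution of
    the true value.  Includes a synthetic-data generator with known ground
    truth, parameter-recovery harnesses, MCMC convergence diagnostics, and
    a command-line driver.  The motivating application is non-invasive
    haemoglobin (SpHb) monitoring against laboratory haemoglobin (tHb).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
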