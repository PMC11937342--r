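Package: sudlearn
Title: Self-Utility Distance and Social Trait-Utility Learning Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the alignment between people's self-concept
    and the perceived utility of their traits. Implements profile-discrepancy
    metrics (Self-Utility Distance and ideal-/ought-self discrepancies), five
    generative models of social trait-utility learning with
    similarity-weighted prediction-error spreading, hierarchical Bayesian
    model fitting with Laplace-approximated evidence and protected exceedance
    probabilities, parameter- and model-recovery diagnostics, and the survey
    association layer (correlations with Fisher confidence intervals,
    hierarchical regression, commonality analysis, variance inflation
    factors, best-subset BIC selection). Includes synthetic-cohort generators
    so every stage can be exercised without access to participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    splines,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
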