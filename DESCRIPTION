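Package: vocalib
Title: Bayesian Calibration of Vocalization Counts from Error-Prone
    Speaker Diarization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying and correcting the downstream effects of
    speaker-classification errors on vocalization counts derived from
    long-form child-centered audio recordings. Couples a hierarchical
    model of children's speech behavior (population, corpus and child
    levels, sibling effects, random age slopes with a 24-month plateau,
    and a long-term input effect) with a model of a voice-type
    classifier's confusion behavior (per-recording Gamma-distributed
    confusion rates and double-Poisson count noise). Supports exact
    marginal likelihoods for human-annotated 15-second calibration
    windows, joint Bayesian calibration by adaptive Markov chain Monte
    Carlo, simulation-based sensitivity analysis and null-hypothesis
    testing, agreement metrics, segment-table input and output, and
    fully synthetic data generation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
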