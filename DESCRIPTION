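Package: aoanet
Title: Connectionist Simulation of Age-of-Acquisition Effects in Word Naming
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the age-of-acquisition (AoA) effect in single-word
    reading with a slot-coded feedforward network that maps orthography to
    phonology. Provides a synthetic quasi-regular lexicon generator with
    grade-of-acquisition structure, frequency and Coltheart-N consistency;
    localist slot encoding and decoding; a two-layer logistic network
    trained by online error back-propagation with momentum or by the
    batch Quickprop secant method; staged training curricula (focused
    early-word training followed by interleaved early/late training,
    order-reversal and hyperparameter controls); graded hidden-unit
    lesioning; and analysis utilities (per-item error scoring, group
    summaries, analysis of covariance with frequency and consistency
    covariates, and sigmoid-saturation plasticity diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
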