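Package: psgres
Title: Resilience Experiments for Fully Convolutional Sleep Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the resilience of U-Sleep-style fully
    convolutional sequence-to-sequence sleep stagers on synthetic
    polysomnography cohorts. Provides a seeded synthetic PSG generator with
    stage-dependent spectra, center and age effects and scorer noise; the
    standard preprocessing chain (resampling, robust per-channel scaling
    with clipping, hypnogram trimming, stage harmonization); AASM-recommended
    and atypical channel derivations; the hierarchical class-balanced
    sampling and augmentation pipeline; a configurable encoder/decoder/
    segment-classifier network with vanilla, categorical conditional and
    sandwich batch normalization; masked cross-entropy training with Adam
    and early stopping, transfer-learning workflows; majority-vote
    evaluation with macro/weighted F1 and Cohen's kappa; and orchestration
    of desk-scale derivation-resilience, center-generalization and
    age-conditioning experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite
Config/testthat/edition: 3
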