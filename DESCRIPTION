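Package: intentprior
Title: Simulation and Analysis of Prior-by-Evidence Interplay in Intention Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse two-alternative intention-inference
    experiments in which an observer's prior expectations compete with graded
    visuomotor evidence. Provides a biased trial-sequence generator emitting
    BIDS-style event tables, a memory-decay Bayesian observer producing
    trial-by-trial prior probabilities, a logistic prior-by-evidence choice
    model with decay-parameter fitting, repeated-measures ANOVA and
    prior-effect summaries, a parametric fMRI design-matrix builder with
    serially orthogonalized modulators and ROI-level GLM fitting,
    psychophysiological-interaction (PPI) regressor construction, and a
    desk-scale bilinear dynamic-causal-modelling (DCM) model space with
    BIC-based evidence and random-effects Bayesian model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
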