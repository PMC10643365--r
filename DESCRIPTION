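Package: repdcm
Title: Dynamic Causal Modelling of Auditory Speech Repetition Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits four-region dynamic causal models (A1, pSTS, pOp, M1) of
    effective connectivity during auditory speech repetition to regional BOLD
    time series. Provides a deterministic neural/balloon-Windkessel forward
    model, variational Laplace (Gaussian fixed-form variational Bayes)
    inversion, analytic Bayesian model reduction over a 256-model space of
    pruned connectivity architectures, parametric empirical Bayes for
    group-level connectivity, and a degeneracy analysis that classifies fitted
    models into groups A-D by their excitatory motor afferents and summarises
    within-subject group membership by Shannon entropy in nats. A synthetic
    cohort generator reproduces the study design (block design, TR 3.085 s,
    66 volumes per run) with known ground-truth architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
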