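Package: somnidyn
Title: State-Dependent LFP and Spiking Dynamics in Long-Term Cortical Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for behavioral-state analysis of chronic
    multichannel cortical recordings. Classifies Move/Rest/REM/NREM states from
    8-second local field potential (LFP) spectra and accelerometry with a stacked
    sparse autoencoder and k-means clustering, and quantifies state-dependent
    neural dynamics: Welch spectra, magnitude-squared coherence and weighted
    phase lag index, cross-frequency phase-amplitude coupling with a normalized
    mean-vector-length statistic, two-window spike discrimination with
    inter-spike-interval cell-type profiling, and spike-field phase locking.
    Includes a seeded synthetic-session generator that plants known states,
    coupling depths and phase-locking parameters so every estimator can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
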