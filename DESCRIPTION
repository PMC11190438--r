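Package: ultradian
Title: Delayed Stochastic Models and Single-Cell Analysis of Ultradian
    Gene Expression Oscillations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for studying ultradian oscillations of Hes/Her family
    transcription factors in developing tissue. Implements stochastic
    delay-differential models of autorepressive gene expression in single
    cells and in hexagonal cell lattices coupled by Notch-Delta lateral
    inhibition (chemical Langevin noise, Euler-Maruyama integration), a
    pattern-search exploration of parameter space for regimes in which
    protein destabilisation increases population heterogeneity, and a
    single-cell fluorescence track analysis pipeline: coefficients of
    variation, trend estimation and detrending, Hilbert peak-to-trough
    fold-change, periodogram coherence, wavelet period estimation with a
    permutation null, Gaussian-process classification of oscillatory
    versus aperiodic tracks with false-discovery-rate control, and
    nearest-neighbour intensity analysis of 3D nuclear snapshots. A
    synthetic-data generator with known ground truth makes every stage of
    the pipeline testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    MASS,
    minpack.lm,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
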