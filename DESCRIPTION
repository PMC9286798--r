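Package: middecode
Title: Single-Trial EEG Decoding of Reward Anticipation in the Monetary
    Incentive Delay Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-trial analysis of cue-locked EEG from the
    (electroencephalographic) monetary incentive delay task. Implements a
    sliding-window regularized Fisher linear discriminant with leave-one-out
    ROC area (Az), label-permutation significance thresholds, forward-model
    scalp topographies, reaction-time-matched salience contrasts, extraction
    of single-trial variability (STV) and its regression onto reaction times
    with a group-level test, classical ERP window amplitudes and difference
    waves, and a cluster-based permutation comparison of Az curves between
    groups. A full task-plus-EEG simulator (adaptive staircase agent model,
    planted valence and salience components) generates synthetic cohorts so
    the whole pipeline can be exercised and validated without real
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    jsonlite,
    MASS,
    emmeans,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
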