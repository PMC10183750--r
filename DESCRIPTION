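Package: oscillatr
Title: Oscillatory EEG Analysis with Aperiodic Correction, Cluster
    Permutation Tests and Theta-Beta Phase-Amplitude Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sensor-space analysis of task-related EEG
    oscillations in within-subject factorial designs. Provides Morlet
    wavelet time-frequency decomposition with iterative 1/f (aperiodic)
    spectral subtraction and baseline normalization, Monte-Carlo
    cluster-based permutation tests over channel space and time, a
    searchlight mini-cluster test of the scalp specificity of a
    region-of-interest effect, theta-beta phase-amplitude coupling via a
    normalized Kullback-Leibler modulation index with balanced trial
    subsampling, behavioral aggregation with repeated-measures ANOVA,
    planned t-tests, Cohen's d and JZS Bayes factors, and a fully seeded
    synthetic EEG and behavior cohort generator so the entire pipeline
    can be exercised and validated without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    tibble,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
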