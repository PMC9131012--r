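Package: microdyn
Title: EEG Microstate Dynamics and Microstate-Specific Phase-Locking Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of resting-state EEG brain dynamics through topographic
    microstates. Provides polarity-invariant modified k-means segmentation of
    scalp maps at global-field-power peaks, Krzanowski-Lai model-order
    selection, template back-fitting with temporal smoothing, the full
    microstate parameter suite (explained variance, duration, occurrence,
    coverage, interval, mean field power, spatial-correlation and transition
    matrices), microstate-specific phase-locking-value connectivity after
    spherical-spline surface-Laplacian filtering, a signed network-based
    statistic permutation framework with Holm correction and BCa bootstrap
    intervals, and nested leave-one-out SVM classification. A semi-Markov
    synthetic EEG generator with planted templates, gamma dwell times and
    von Mises phase coupling supplies ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    pROC,
    boot,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
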