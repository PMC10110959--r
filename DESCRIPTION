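Package: modewalk
Title: Discovery of Discrete Migration Modes in Single-Cell Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for long-term two-dimensional single-cell migration
    tracks: gap interpolation and splitting, three-criteria track
    filtering, hour-scale trajectory segmentation, five shape and dynamics
    descriptors per segment (radius of gyration, asphericity, kinetic
    energy, end-to-end distance, turning-angle variance), a hybrid
    unsupervised/supervised kernel (silhouette-scanned K-means
    pseudo-labels refined by a gradient-boosted classifier) that discovers
    and annotates discrete migration modes, trajectory statistics
    (time-averaged mean squared displacement and anomalous exponent,
    displacement distributions, turning-angle heatmaps, phase-space
    densities, zigzag fractions), mode-transition analytics (transition
    matrices, dwell times, one- and two-step pathways), and a synthetic
    mode-switching trajectory simulator for end-to-end validation.
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
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
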