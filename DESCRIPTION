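Package: scanpathcmp
Title: Multi-Participant Scanpath Comparison for AOI-Based Eye Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing visual scanpaths of many participants over a
    shared stimulus segmented into areas of interest (AOIs). Builds AOI token
    sequences from fixation tables, collapses repeated fixations, computes
    pairwise Levenshtein distance matrices normalised for simultaneous
    visualisation, derives data-driven dwell-time grids from DBSCAN core-point
    radii, counts directed AOI transition frequencies, and compares groups with
    nonparametric Mann-Whitney tests under Bonferroni correction. Includes a
    seeded Markov-chain gaze simulator emulating a multi-participant ECG
    interpretation study, figure renderers for distance matrices, web (radar)
    diagrams, gridded heatmaps and chord diagrams, and a command-line entry
    point covering the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
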