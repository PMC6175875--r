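Package: tubesta
Title: Subtomogram Averaging of Helical Coat Lattices on Membrane Tubes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale cryo-electron tomography pipeline for membrane
    tubes decorated with helical protein coats. Simulates ground-truth
    tubules, coat lattices and dose-symmetric tilt series with contrast
    transfer and noise; reconstructs tomograms by weighted back-projection
    with exposure filtering and phase-flip CTF correction; seeds particles
    on tube surfaces with membrane-normal orientation priors; performs
    missing-wedge-aware iterative subtomogram alignment with particle
    curation (duplicate suppression, per-tube directionality, azimuth-
    dependent cross-correlation weighting) and independent half-set
    refinement; assesses resolution by mask-corrected Fourier shell
    correlation; and computes normalized model-versus-map difference maps
    with blob detection. Particle metadata flows through tidy tabular
    structures; density volumes use a lightweight MRC2014-backed class.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
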