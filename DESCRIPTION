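Package: cellbright
Title: Per-Cell Protein Level Estimation from Phase-Contrast Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates per-cell biomarker protein levels from label-free
    phase-contrast microscopy images of adherent cells (in-silico
    immunostaining). Cells are segmented from a membrane-fluorescence
    channel by thresholding and connected-component labeling; marker
    fluorescence is converted to area-normalized per-cell mean images; a
    convolutional encoder-decoder (U-Net) is trained to regress those
    target images from phase contrast; trained models are applied per cell
    to single fields and to live-cell time-lapse sequences, with Pearson
    evaluation, paired-condition comparison, trajectory linking, and
    density/event-response analyses. Includes a seeded synthetic scene
    simulator with ground truth so the entire pipeline is testable without
    microscope data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
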