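Package: substacks
Title: Cell Segmentation from Hyper-Labeled Microscopy Stacks via Loading Codes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and evaluates cell-segmentation models on three-channel
    subimage stacks assembled on the fly from multi-channel ("hyper-labeled")
    microscope image stacks. Loading codes describe how each input channel is
    built (simple load, random choice among channels, channel merging) and how
    channel dropout and merge dropout perturb it, so that a single dataset of
    co-registered fluorescence and multi-focal brightfield images can emulate a
    wide range of labeling conditions. Includes a synthetic microscopy
    simulator with ground-truth masks, multi-page TIFF and PNG mask I/O, a
    ResNet-encoder U-Net with a pixel-shuffle decoder trained under a weighted
    cross-entropy loss and a two-phase 1-cycle schedule, and evaluation
    protocols for strategy comparison and train-by-validate dropout robustness
    sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    png,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
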