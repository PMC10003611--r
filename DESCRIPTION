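Package: astromorph
Title: Quantification of Astrocyte Number and Branching in DAB-Stained
    Photomicrographs
Version: 0.1.0
Authors@R: person("Astromorph", "Maintainers",
    email = "astromorph@example.org", role = c("aut", "cre"))
Description: Semi-automatic quantification of GFAP-labelled astrocytes in
    brightfield immunohistochemistry photomicrographs taken at low
    magnification (~20x). Implements the full analysis chain natively:
    image loading and 8-bit conversion with micrometer calibration, FFT
    bandpass filtering, unsharp masking and despeckling, maximum-entropy
    (Kapur) thresholding with morphological mask cleanup, topology
    preserving skeletonization, skeleton-graph branch extraction with
    calibrated branch lengths, and the spreadsheet-style data trimming
    that removes one-branch skeletons and aggregates per-cell, per-image,
    per-zone and per-group statistics (branches per cell, cells per area,
    branch length per cell, binned branch-length distributions and
    virtual cell size scatter tables). Includes a synthetic
    photomicrograph generator with exact ground truth and a batch
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
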