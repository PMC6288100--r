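Package: fretflow
Title: Spatio-Temporal Analysis of Ratiometric FRET Imaging Under Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies stimulus-induced changes in intramolecular FRET
    biosensor activity from two-channel (donor/FRET) time-lapse microscopy of
    single adherent cells exposed to laminar flow. Provides corner-based
    background estimation and subtraction, median despeckling, Otsu
    segmentation of the cell, per-pixel FRET/donor ratio maps, whole-cell
    ratio time series with pre-stimulus baseline normalization, division of
    the cell into equal-width bins along the flow axis with per-bin
    fluorescence percentages, upstream/downstream polarity testing across
    replicate cells by two-tailed t-test, assembly of bin-by-time
    spatio-temporal maps, and in-vitro emission-spectrum ratio computation.
    Includes a synthetic two-channel acquisition generator with known ground
    truth (ratio decay, flow-axis gradient, photon and read noise,
    photobleaching) for validation and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
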