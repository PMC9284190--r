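Package: ChromaPlex
Title: RGB-Fingerprint Spectral Unmixing for Cyclic Multiplexed
    Immunofluorescence on a Color Sensor
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@chromaplex.dev",
           role = c("aut", "cre"))
Description: Analysis stack for cyclic multiplexed immunofluorescence
    acquired with LED-sequential illumination, a multi-passband (penta)
    emission filter and an RGB (Bayer) camera. Models the optical chain
    (LED emission, excitation filters, fluorochrome excitation/emission,
    penta transmission, sensor channel sensitivities) to predict or
    estimate the per-fluorochrome RGB fingerprint matrix, unmixes pixel
    signals by non-negative linear least squares (S = AF with F bounded
    below by zero), and carries images through the full per-cell
    pipeline: dark-frame subtraction, cycle-to-reference rigid
    registration on the DAPI channel, quench/autofluorescence
    subtraction, nucleus and cell segmentation with quality-control
    filters, per-cell marker quantification, percentile normalization,
    IgG-based positivity calling and rule-based phenotyping. A seeded
    optical forward simulator (cells, beads, focus stacks, noise,
    inter-cycle misalignment) makes every stage testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse,
    ggplot2
Config/testthat/edition: 3
biocViews: Software, CellBasedAssays, Preprocessing, Spectroscopy,
    SingleCell, ImmunoOncology
RoxygenNote: 7.3.3
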