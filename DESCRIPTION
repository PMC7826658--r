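Package: perfmap
Title: Quantitative Perfusion Cartography from Fluorescence and
    Hyperspectral Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantitative intraoperative perfusion assessment
    from optical imaging. Computes pixel-wise time-to-peak slope
    cartography from indocyanine-green fluorescence video stacks with
    reference-card normalization, registers static tissue oxygen
    saturation (StO2) maps onto the fluorescence cartography with
    moving-least-squares landmark warping, quantifies capillary density
    from confocal endomicroscopy frames (FCD-A index), and fits
    exponential models predicting local capillary lactate from either
    perfusion metric, with leave-one-subject-out cross-validation,
    paired Wilcoxon model comparison, Spearman correlation and
    correlation-based sample-size calculation. A synthetic-data
    generator emulating a three-zone partial-ischemia experiment
    provides ground-truth inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tiff,
    jsonlite,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
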