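Package: sorsbone
Title: Spatially Offset Raman Spectroscopy Analysis of Bone Mineral and
    Matrix Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and chemometric analysis of spatially offset Raman
    spectroscopy (SORS) measurements of cortical bone. Converts raw CCD
    detector frames into calibrated bundle spectra (dark subtraction,
    smile rectification against neon and acetaminophen calibration peaks,
    neon/acetaminophen wavenumber-axis calibration solving the effective
    laser wavelength, white-lamp fixed-pattern and green-glass broadband
    response correction), cleans replicate spectra (median-absolute-
    deviation cosmic-ray rejection, iterative modified-polynomial
    fluorescence removal, noise-floor clipping), quantifies phosphate-
    normalized mineral-to-matrix band ratios with pairwise group
    statistics, and predicts DXA T-scores by leave-one-out cross-validated
    partial least squares regression with WHO classification. A synthetic
    cohort and instrument simulator with known ground truth makes every
    stage testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
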