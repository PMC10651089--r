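Package: psfqc
Title: Automated Point Spread Function Analysis for Microscope Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated measurement of microscope point spread functions
    from 3D image stacks of sub-resolution fluorescent beads. Detects features
    without user-set parameters via a multi-scale difference-of-Gaussians
    representation, minimum cross-entropy (Li) thresholding and 3D local
    maxima; fits 2D elliptical and 1D Gaussian models to recover lateral and
    axial full width at half maximum; maps inclined-ellipse widths to image-axis
    projections; and ships a synthetic 3D Gaussian bead simulator with Poisson
    noise plus a percentage-RMSE benchmark for validating PSF analyzers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    tiff,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
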