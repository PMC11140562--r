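Package: cctaphantom
Title: Structured Digital Phantom Analysis for Coronary CT Angiography
    Image Quality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates a digital anthropomorphic cardiac phantom for coronary
    CT angiography image-quality assessment, emulates reconstructed images
    with the second-order statistics (point-spread function, noise magnitude
    and noise power spectrum shape) of hybrid iterative, deep-learning and
    super-resolution deep-learning reconstruction families, and measures
    image quality against the analytic ground truth: region-of-interest
    noise standard deviation, the two-dimensional noise power spectrum,
    task-based modulation transfer functions in-plane and along the scanner
    axis, and vessel/stent profile-curve metrics (peak CT number, threshold
    widths, stent lumen width), plus CTDIvol/DLP effective-dose conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
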