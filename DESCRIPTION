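Package: fluorspot
Title: Grid-Based Quantification of Fluorescent Microarray Spot Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale analysis of scanned fluorescence microarray images:
    reads TIFF/PNG/JPEG scans, converts colour scans to greyscale with
    standard luminance weights, partitions the image into a user-declared
    rows-by-columns grid of cells, binarizes each cell with Otsu's method
    (or one of a suite of classic histogram thresholding methods, globally
    or per cell), and reports background-corrected spot intensities.
    Includes Spearman rank correlation, linear calibration and two-group
    comparison utilities for validating pipeline output against reference
    measurements, and a seeded synthetic array-image generator with ground
    truth for end-to-end testing of spot recovery on non-uniform
    backgrounds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    tiff,
    png,
    jpeg
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
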