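Package: temsizer
Title: Size Measurement of Particulate Nanomaterials from TEM Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for number-based size measurement of particulate
    (nano)materials from calibrated transmission electron micrographs.
    Implements morphology-specific segmentation of constituent particles
    (default watershed, irregular watershed with convexity-driven merging,
    ellipse fitting, and single-particle modes), exact minimal/maximal
    Feret diameters via rotating calipers on pixel-corner convex hulls,
    working-range rules (limit of detection and quantification limits
    tied to pixel size and field of view), per-specimen size distribution
    summaries, a top-down ANOVA measurement-uncertainty budget with
    trueness assessment against certified reference values, ruggedness
    analysis versus particle count, and ISO 5725-2 style interlaboratory
    precision statistics with Cochran and Grubbs outlier screening.
    A synthetic micrograph generator with exact ground truth supports
    end-to-end verification of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    pracma,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
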