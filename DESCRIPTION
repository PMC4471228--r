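Package: spiFootprint
Title: Sediment Profile Imagery Analysis of Aquaculture Sulfide Footprints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Locates the benthic sulfide footprint of suspended shellfish
    farms from sediment profile images. Provides calibrated colour-intensity
    extraction (calibration-strip affine correction, HSI intensity, surface
    contour detection, rectangle or contour-following regions of interest),
    conversion of mean grey values to acid volatile sulfide (AVS)
    concentration estimates with validity-range flagging, a
    plateau-constrained segmented regression that estimates the footprint
    boundary with bootstrap or delta-method confidence intervals, ANCOVA and
    Tukey-Kramer transect comparisons, and spatial interpolation of grey
    values into a footprint raster with iso-contour extraction. A synthetic
    data generator with known ground truth makes the whole workflow testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    graphics,
    utils,
    tools,
    png,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jpeg,
    multcomp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
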