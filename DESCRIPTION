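Package: afmetrics
Title: Metrology Toolbox for Scanning Force Microscopy Images of Biomolecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scriptable metrology for scanning force microscopy (SFM/AFM)
    height maps of DNA and protein complexes. Reads NanoScope, JPK-TIFF,
    Igor binary wave, ASCII x-y-z and generic raster images into a single
    calibrated height-map representation; segments particles by thresholding
    the Sobel gradient magnitude followed by morphological cleanup; measures
    background-subtracted particle volume, freehand path length, height and
    width (Gaussian FWHM) profiles, skeleton contour length and angles; and
    performs high-throughput per-particle statistics with volume histograms
    and optional calibration to molecular mass. Ships a synthetic ground-truth
    image generator and fixture writers for every supported file dialect.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    igraph,
    minpack.lm,
    png,
    tiff,
    jpeg,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
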