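Package: fembow
Title: Radiographic Measurement of Femoral Sagittal Bowing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computerized measurement of the sagittal (anterior) bowing of the
    femur from annotated lateral radiographs. Given operator-traced border
    polylines of the femoral shaft outline and the medullary canal plus three
    anatomical seed landmarks, the package constructs the remaining measurement
    endpoints, extracts the central line between each border pair by two-seed
    equal-speed region-growing territory propagation on a raster grid, and fits
    least-squares circles to the whole central line and its three equal
    arc-length segments to report radii of curvature in millimetres. Includes a
    synthetic phantom generator with known ground-truth radii, repeatability
    statistics (coefficient of variation, group means, Welch comparisons), a
    reference dataset from a ten-radiograph validation series, annotation and
    measurement file formats, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
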