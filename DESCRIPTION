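Package: vesselunwrap
Title: Unwrapping and Junction Phenotype Analysis of 3D Microvessel Image Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs a cylindrical endothelial monolayer from confocal
    z-stacks of a microvessel, fits a lumen circle to user waypoints,
    unwraps the vessel surface into a flat 2D sheet, and quantifies
    cell-cell junction phenotypes (continuous, punctate, perpendicular),
    junction coverage, and cell morphology (area, perimeter, circularity,
    solidity) per cell. Includes an intensity-guided minimum-cost border
    tracer, a synthetic vessel generator with analytic ground truth for
    end-to-end validation, and group statistics (D'Agostino-Pearson
    normality screen, two-sample tests, star annotation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    grDevices,
    graphics,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
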