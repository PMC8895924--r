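Package: femurmetrics
Title: Proximal Femur Morphometry and Cephalomedullary Nail Compatibility
Version: 0.1.0
Authors@R: person("femurmetrics", "developers", role = c("aut", "cre"),
    email = "femurmetrics@example.org")
Description: Computes a planar-corrected geometric profile of the proximal
    femur from 3D landmark sets: the femur neck-shaft axis offset (FNSAO,
    the common-perpendicular distance between the skew neck and proximal
    shaft axes), the distance from the greater trochanter tip to the axes'
    point of closest proximity, neck axis length, three neck-shaft angle
    variants, femoral anteversion against the posterior condylar axis, and
    the intramedullary radius of curvature. Includes a parametric synthetic
    femur generator for desk-scale cohort simulation with known ground
    truth, a cephalomedullary nail catalog with anatomy-implant mismatch
    reporting, and a cohort statistics stage (descriptives with confidence
    intervals, normality-gated two-group tests, correlation screens).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
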