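Package: concord
Title: Interrater Contour Agreement Analysis for Radiotherapy Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies interobserver agreement of 3D structure delineations
    (contours) drawn by multiple raters on volumetric medical images, as used
    in radiotherapy contour quality assurance. Computes the Dice similarity
    coefficient, symmetric 3D average surface distance, and Hausdorff distance
    over all rater pairs, after harmonizing each structure's contours to their
    maximal common superior-inferior extent and optionally deriving
    inferior-half subsets. Includes a seeded synthetic phantom-cohort
    generator with a parameterized rater-noise model (surface displacement,
    systematic margin bias, cranio-caudal extent jitter) so the full pipeline
    can be exercised against known ground truth, and emits median/IQR summary
    report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
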