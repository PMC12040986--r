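Package: volagree
Title: Volumetric Agreement Limits and Clinimetric Reliability of
    Automated Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Clinimetric reliability analysis for automated tumor
    volumetry. Computes geometric segmentation metrics (Dice, average
    symmetric surface distance, 95th-percentile Hausdorff distance,
    relative volume error) from 3D binary label maps with physical voxel
    spacing; estimates multi-observer limits of agreement with the mean
    (LOAM) with Monte Carlo confidence intervals from subject-by-observer
    volume matrices; builds volume-dependent agreement bands with a
    sliding window; classifies a candidate (e.g. AI) annotator's volumes
    against the human upper agreement limit; and re-estimates agreement
    limits with the candidate included as an additional observer.
    Includes seeded synthetic generators (lognormal volume matrices and
    3D ellipsoid phantom masks) so the whole pipeline is testable without
    clinical imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
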