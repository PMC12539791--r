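Package: atlaswarp
Title: Self-Supervised Atlas-Based Segmentation by Deformable Registration
Version: 0.1.0
Authors@R:
    person("Atlaswarp", "Developers", email = "atlaswarp@example.org",
           role = c("aut", "cre"))
Description: Tools for atlas-based segmentation of single anatomical
    structures in 3D CT volumes via self-supervised deformable registration.
    A convolutional network regresses a dense displacement field mapping a
    reference atlas onto each target volume; training combines a
    cross-correlation image-similarity loss, an (optionally
    distance-weighted) displacement-smoothness penalty, and a
    Mumford-Shah-style intra-class intensity-variance term so that the
    transferred atlas mask lands on a homogeneous image region. Includes
    NIfTI-1 I/O, intensity windowing and cube cropping, warping and surface
    transfer utilities, Dice and 95th-percentile Hausdorff evaluation with
    exclusion regions, a greedy loss-weight sweep, a seeded multi-trial
    protocol, and a phantom generator for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
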