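Package: tomoshot
Title: One-Shot Classification and Attention-Guided Segmentation of
    Cryo-ET Subtomograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A Siamese one-shot learning framework for cryo-electron
    tomography. Matches a target subtomogram against an n-class
    single-example support set while simultaneously producing a
    voxel-level macromolecule segmentation, refined by a fully connected
    3D conditional random field. Includes a realistic subtomogram
    simulator (random poses, tilt-limited projection with missing wedge,
    CTF/MTF optical factors, additive noise at a target SNR, weighted
    back-projection reconstruction) and geometric phantom generation for
    fully reproducible experiments without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
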