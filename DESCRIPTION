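Package: serialreg
Title: Expert-Supervised Rigid Registration of Bone Models for Serial Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to position triangulated bone surface models in a second
    image frame from sparse, manually placed attraction points using rigid
    coherent point drift (CPD), and to evaluate the resulting registrations
    against fiducial-marker (Kabsch) and whole-model reference registrations.
    Includes lofting of per-slice closed B-spline contours into closed
    triangulated meshes, mean absolute surface distance and volumetric Dice
    metrics with a voxelizer, a synthetic generator of bone-like meshes with
    simulated operator point placement and interoperator segmentation
    perturbation, and study harnesses for attraction-point-count and
    method-comparison experiments with rank-based statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    RNifti,
    splines,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
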