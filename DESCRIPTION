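Package: thromboflow
Title: Time-Corrected Thrombus Reconstruction and Lagrangian Platelet Shear Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs time-corrected instantaneous 3D surfaces of growing
    wall-attached thrombi from time-skewed confocal z-stacks, quantifies
    surface growth by bidirectional normal-ray distance mapping, solves steady
    incompressible flow in a rectangular microcapillary around the
    reconstructed surface, and computes the Lagrangian shear-rate history that
    platelets experience along backward-integrated pathlines before adhesion.
    Includes a synthetic phantom module that emulates confocal acquisition of
    growing thrombus-like geometries, so every stage can be validated against
    exact ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    tiff,
    yaml,
    tibble,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
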