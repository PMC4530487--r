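Package: bonefe
Title: Voxel-Based Micro-Finite-Element Analysis of Whole-Bone Bending
    Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An image-based pipeline for whole-bone biomechanics: synthetic
    micro-CT femur phantoms, the standard preprocessing chain (reorientation,
    block-mean resolution reduction, per-mille thresholding, crop to the
    bending span, connected-component cleanup), voxel-conversion hexahedral
    micro-finite-element models of a three-point bending test solved with a
    matrix-free element-by-element preconditioned conjugate gradient method,
    load-displacement curve analysis (elastic stiffness, yield load, ultimate
    load), back-calculation of the bone tissue Young's modulus from the
    experiment-to-model stiffness ratio, and paired Wilcoxon signed-rank and
    t-test statistics for treated versus contralateral control bones.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    Rcpp,
    RNifti,
    tiff,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'accessors.R'
    'bonefe-package.R'
    'constructors.R'
    'calib.R'
    'mechtest.R'
    'microfe-element.R'
    'microfe-model.R'
    'microfe-solve.R'
    'imageproc.R'
    'pipeline.R'
    'cli.R'
    'io-vtk.R'
    'phantoms.R'
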