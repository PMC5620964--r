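Package: tuns
Title: Non-Rigid Structure from Motion with Kernelized Low-Rank Representation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Recovers per-frame 3D joint positions of an articulated body from
    monocular 2D joint tracks and known orthographic camera rotations. The
    reconstruction minimizes a kernelized low-rank representation objective
    with a nuclear-norm shape prior, an L1 reprojection error and a soft
    bone-inextensibility penalty, solved by an augmented Lagrangian multiplier
    (ALM) scheme with singular-value thresholding and shrinkage proximal
    steps. Includes a marker-less variant driven by per-joint detector
    heightmaps, scale-normalized reconstruction error metrics, subspace
    clustering of the recovered affinity matrix, a forward-kinematics
    synthetic motion generator for offline testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
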