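Package: mc3ssm
Title: Statistical Shape and Bone Mineral Density Modelling of the Equine
    Distal Third Metacarpal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to build combined statistical shape and subchondral bone
    mineral density models of the equine distal third metacarpal (MC3)
    epiphysis from calibrated CT data. Implements a piecewise-parametric
    cubic Lagrange template surface, host-mesh (free-form deformation)
    registration to segmented point clouds, iterative shape-model-constrained
    correspondence refinement, phantom-based Hounsfield-unit to
    hydroxyapatite-equivalent density calibration, subchondral density
    sampling along inward surface normals, covariance and correlation based
    principal component models of shape, density and combined shape-density
    variation, leave-one-out reconstruction analysis, and landmark
    morphometry. Ships a synthetic MC3-like population generator with known
    latent modes so every pipeline stage can be validated against ground
    truth without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    RNifti,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
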