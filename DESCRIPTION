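Package: nonunionFE
Title: Voxel Finite-Element Analysis of the Minimal Fusion Area of Plated Nonunions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based voxel finite-element pipeline for fracture-nonunion
    biomechanics. Generates synthetic CT-like phantoms of a plated long bone
    with a transverse nonunion gap, segments tissue classes by anisotropic
    diffusion and thresholding, coarsens the image grid by block averaging,
    maps grayscale to elastic constants through a Hounsfield calibration and
    a density power law, solves linear elasticity on hexahedral voxel meshes
    under axial load, and iteratively demotes low-stress nonunion cells to
    soft tissue to identify the minimal set of fusion voxels that keeps the
    scaled von Mises stress in the implant below a stop criterion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    Matrix,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'configs.R'
    'fem.R'
    'imaging.R'
    'io.R'
    'materials.R'
    'optimize.R'
    'phantom.R'
    'pipeline.R'
    'vtk.R'
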