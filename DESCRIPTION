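Package: scaffoldlab
Title: Morphology, Stiffness and Permeability of TPMS and Strut-Based Bone Scaffolds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates triply periodic minimal surface (TPMS) and strut-lattice
    bone-scaffold unit cells from implicit nodal equations, calibrates the
    level-set constant to a target porosity, and characterizes the resulting
    microstructures: porosity and surface-to-volume ratio by iso-surface
    morphometry, effective compressive and shear moduli by voxel-based periodic
    homogenization with a two-phase (solid/soft-void) material model, and Darcy
    permeability by a staggered-grid Stokes solve on the void domain together
    with the Kozeny-Carman estimate. Scaling laws relating the properties to
    porosity (Gibson-Ashby modulus-density power law, quadratic
    surface-to-volume relations, exponential permeability-porosity relations,
    shear-versus-compression linear relations) are fitted and returned as
    classed model objects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
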