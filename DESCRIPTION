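Package: iscatsim
Title: Simulation of Interferometric Scattering, Coherent Bright-Field, and
    Dark-Field Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unified simulation platform for interference microscopy of
    nanoparticles near a planar substrate.  Scattered fields are computed with
    point-dipole models, Mie theory, or a Galerkin boundary element method
    (PMCHWT formulation) for arbitrary triangulated particles; planar layer
    stacks are treated with Fresnel transfer matrices and a far-field interface
    correction.  Reference and scattered fields are imaged through a high-NA
    aplanatic two-lens system via the vectorial Richards-Wolf diffraction
    integral, with optional Jones-matrix manipulations (waveplates,
    attenuators, beam blocks) in the back focal plane.  The package assembles
    iSCAT, COBRI, and dark-field camera images, contrast and phase maps,
    focal stacks, correlation-based focus estimation, Michelson contrast,
    Brewster-angle contrast tuning, partial longitudinal coherence, and
    confocal scanning excitation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
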