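Package: darcypar
Title: Parameterising Multi-Compartment Darcy Perfusion Models from
    Discrete Vascular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving continuum porous-media (Darcy) perfusion
    parameters from one-dimensional vascular networks. Provides seeded
    generators for volume-filling bifurcating trees and anisotropic
    capillary lattices, a sparse Poiseuille network flow solver,
    hierarchic-parameter partitioning of vessels into compartments,
    spherical representative-volume-element averaging of pressure,
    porosity and inter-compartment flux, three permeability-tensor
    parameterisation methods (porosity-scaled isotropic, Huyghe-Van
    Campen, projected PCA), a trilinear hexahedral finite-element solver
    for the coupled multi-compartment Darcy system, and evaluation
    drivers comparing the continuum pressure against the spatially
    averaged discrete solution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
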