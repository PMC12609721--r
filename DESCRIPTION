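Package: MembraneMC
Title: Metropolis Monte Carlo Simulation of Deformable Membranes Coupled
    to Stochastic Molecular Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A spatial stochastic simulator that couples diffusing
    particles and surface-bound receptor/ligand molecules to deformable
    triangulated membranes through Metropolis Monte Carlo dynamics.
    Particle collisions drive a piston membrane, elastic stretching and
    pressure energies govern membrane node moves, and distance-gated
    receptor-ligand binding feeds adhesion back into membrane dynamics,
    yielding emergent cell spreading on an activating surface. Includes
    mesh generators (icospheres with ruffles, flat grids), Wavefront OBJ
    input/output, turn-key scenario runners (piston chamber, fluctuating
    membrane, cell-cell contact, T cell spreading), observable logging
    and a diffusion-coefficient estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'MembraneMC-package.R'
    'RcppExports.R'
    'accessors.R'
    'mesh-geometry.R'
    'molecules.R'
    'energetics.R'
    'config.R'
    'mc-engine.R'
    'mesh-generators.R'
    'mesh-io.R'
    'observables.R'
    'particles.R'
    'scenarios.R'
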