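Package: phyllodome
Title: Mechanochemical Phase-Field Simulation of Phyllotaxis on a Growing Dome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the emergence of whorled, spiral and ribbed phyllotactic
    patterns on a growing shoot-apical-meristem-like dome. A two-morphogen
    reaction-diffusion (BVAM) system supplies an auxin-like field that sets a
    spontaneous curvature in a conserved (Cahn-Hilliard-type) phase-field free
    energy; the stress tensor derived from that free energy in turn directs the
    anisotropic transport of the morphogen. Includes second-order finite
    difference operators on regular 3D grids, linear-stability tools for the
    reaction-diffusion kinetics (dispersion relation, Turing band, spherical
    harmonic mode selection), the coupled two-time-scale integrator with tip
    growth and primordium sources, isosurface extraction with mean-curvature
    mapping, primordium detection and symmetry/pattern classification, and
    configuration, snapshot and VTK/PLY/CSV export utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
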