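Package: ShapePolarity
Title: Reaction-Diffusion Simulation of Rho GTPase Cell Polarization on
    Static Cell Shapes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Finite-volume simulation of a mass-conserved Rho GTPase
    (Cdc42, Rac, Rho) and phosphoinositide (PIP, PIP2, PIP3)
    reaction-diffusion network on rasterized two-dimensional cell
    geometries with no-flux boundaries. Provides parametric generators for
    micropattern-style cell shapes (circle, ellipse, rectangle, teardrop,
    drops, triangle), transient graded Cdc42 activation stimuli, an
    operator-splitting PDE solver with implicit diffusion, tracking and
    classification of polarization patterns (normal, reverse, uniform;
    front counting), and drivers for aspect-ratio, sensitivity and
    phase-diagram parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    Matrix,
    Rcpp,
    deSolve,
    png,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
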