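Package: afm3d
Title: Three-Dimensional Nanomechanical Characterization from AFM Force Volumes
Version: 0.1.0
Authors@R:
    person("Force Spectroscopy", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for depth-resolved elasticity analysis of atomic force
    microscopy (AFM) force-volume data. Fits Hertzian and Sneddon contact
    models to force-indentation curves, estimates the depth-dependent average
    Young's modulus at every pixel of a force-volume grid, assembles
    depth-sliced modulus map stacks, summarizes each depth slice with a
    Gaussian (mu, sigma) fit and its (mu, sigma, h) vector, and classifies
    softening/stiffening and homogenizing behavior. Includes a synthetic
    force-volume simulator with retained ground truth for validation, text
    based curve/grid input-output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
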