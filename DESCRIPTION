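Package: ridgesim
Title: Anisotropic Interaction Particle Model for Fingerprint Ridge Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the rearrangement of Merkel cells into fingerprint
    ridge patterns with an anisotropic repulsion-attraction particle model on
    the unit torus. Interaction forces are resolved along the local directions
    of smallest and largest stress of an underlying tensor field, which can be
    specified analytically (homogeneous angles, quadratic-differential core and
    delta singularities, piecewise regions) or as a sampled angle grid.
    Includes Kuecken-Champod style and damped-harmonic-oscillator force
    families, explicit Euler and fixed-step Dormand-Prince integration with
    cell-list neighbour search, steady-state verification of equidistant line
    patterns, ridge-spacing measurement with force rescaling, and synthetic
    fixtures (stripe images, structure-tensor orientation estimation, particle
    rendering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
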