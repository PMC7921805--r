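Package: kchtow
Title: Tug-of-War Simulation and Run Analysis of Sperm Cell Transport in
    Pollen Tubes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact stochastic (Gillespie) simulation of bidirectional cargo
    transport by two antagonistic teams of kinesin motors drawing on one
    shared motor pool, as proposed for KCH-kinesin-driven sperm cell movement
    inside growing pollen tubes, together with the matching trajectory
    analysis pipeline used on particle-tracking output: point-to-point
    displacements, run/pause segmentation at a velocity threshold,
    displacement-weighted velocity distributions with Gaussian fits, run
    duration statistics, and paired cohort comparisons.  A synthetic track
    generator emulating tracker output with known ground truth makes the
    analysis stage testable on its own.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
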