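Package: cvinverse
Title: Thin-Layer Cyclic Voltammetry Simulation and Inverse Learning of
    Biosensor Interface Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A data-driven mechanistic toolkit for label-free electrochemical
    biosensors. Simulates cyclic voltammetry (CV) of a single-electron redox
    probe by an implicit finite-volume solution of the one-dimensional
    diffusion equation with a Butler-Volmer electrode boundary condition,
    solved with a tridiagonal (Thomas) algorithm. A multi-objective elitist
    genetic algorithm inverts measured voltammograms for the four interface
    parameters (apparent diffusion coefficient, heterogeneous rate constant,
    charge-transfer coefficient, electrochemically active surface area) by
    minimising the relative errors of oxidation peak current, reduction peak
    current and peak-to-peak separation. Downstream assay statistics include
    four-parameter logistic (4PL) calibration, the IUPAC 3.3-sigma limit of
    detection, signal-to-noise ratio against interferents, and the
    Brown-Anson surface concentration. Voltammograms, configurations and
    calibration tables are plain delimited text; a seeded synthetic-trace
    generator supports testing and method development.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
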