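Package: graphmm
Title: Graph-Neural-Network Parameterization of Molecular Mechanics Force Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end differentiable engine for assigning molecular
    mechanics (MM) force-field parameters to small organic molecules. A
    message-passing graph neural network perceives atomic chemical
    environments from the molecular graph; symmetry-preserving (Janossy)
    pooling builds bond, angle and proper/improper torsion representations;
    and neural readouts emit harmonic bond/angle parameters via a linear
    basis, cosine-series torsion amplitudes with fixed zero phases, optional
    Lennard-Jones parameters, and partial charges through an analytically
    solved charge-equilibration model. The whole pipeline is trainable from
    snapshot energies and reference charges with hand-derived exact
    gradients, and ships a rule-based toy reference force field plus a
    seeded molecule/conformation generator so every experiment runs from
    synthetic data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    utils,
    tools,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
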