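Package: codepend
Title: Compartmental Dynamics and Optimal Control of Drinking-Smoking
    Co-Dependence
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for a seven-compartment social-contagion model of alcohol
    drinking, tobacco smoking and their co-dependence, with temporary recovery
    and relapse. Provides the uncontrolled dynamics with a fixed-step
    fourth-order Runge-Kutta integrator, closed-form and next-generation-matrix
    basic reproduction numbers, equilibrium reports with Jacobian-based
    stability verdicts, local (normalized forward index) and global (Latin
    hypercube sampling with partial rank correlation) sensitivity analysis of
    the reproduction numbers and trajectories, and a five-control Pontryagin
    optimal-control problem solved by a forward-backward sweep. A small
    command-line interface exposes the main analyses as subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite
Config/testthat/edition: 3
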