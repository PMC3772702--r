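Package: meioticODE
Title: Dynamic Model of Yeast Meiotic Initiation Signaling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of a six-variable nonlinear ordinary
    differential equation model of the signaling network that initiates
    meiosis (sporulation) in budding yeast, covering Rim11, Ume6, Sok2,
    Ime1 and Ime2. Provides the kinetic model with its analytic Jacobian,
    numerical integration and steady-state solving, in-silico single-gene
    knockouts and feedback-loop perturbations, equilibrium continuation
    with stability classification and bistable-interval detection,
    multi-parametric global sensitivity analysis (Latin hypercube sampling
    with Kolmogorov-Smirnov sensitivities), and a synthetic validation
    pipeline correlating simulated steady-state Ime2 with
    sporulation-efficiency ratios across knockout genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    deSolve,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
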