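Package: srnaqic
Title: Quasi-Integral Feedback Control of Gene Expression via sRNA-Mediated mRNA Silencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic ODE model of a transcriptional device whose protein
    output adapts to changes in free-ribosome availability through an
    sRNA-mediated post-transcriptional feedback controller. The sRNA and its
    target mRNA annihilate by coupled degradation, so their difference acts as
    a leaky integrator of the tracking error (an antithetic integral motif);
    when all controller reactions are much faster than RNA decay the circuit
    implements quasi-integral control. The package provides the regulated,
    unregulated, full (explicit sensor protein) and ideal-integral model
    variants, closed-form and numeric steady states, stiff time-domain
    simulation with piecewise-constant disturbance profiles, controller
    diagnostics (robustness, quasi-integral design conditions, integrator
    leakiness residual, adaptation error), gain and disturbance sweeps, an
    open-loop silencing dose-response, a registry of named device fixtures,
    YAML experiment configs and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
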