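Package: preqkin
Title: Pre-Equilibrium Titration Analysis of Enzyme Inhibitor Binding
    Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Determines association and dissociation rate constants (k_on,
    k_off) and the equilibrium inhibition constant K_i of tight-binding
    enzyme inhibitors from families of inhibition titration curves recorded
    before binding equilibrium is reached.  Implements the closed-form
    integrated 1:1 binding model, Morrison-type equilibrium tight-binding
    analysis, global nonlinear least-squares fitting with rate constants
    shared across incubation timepoints, a titration and progress-trace
    simulator, and initial-rate extraction from raw fluorescence traces
    with linearity and substrate-depletion quality controls.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
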