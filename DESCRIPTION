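Package: kinlogic
Title: Kinetic Logic and Hybrid Petri Net Modeling of Gene Regulatory
    Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discrete kinetic-logic (Rene Thomas) modeling of biological
    regulatory networks with asynchronous state-graph dynamics, CTL model
    checking and logical-parameter synthesis, state-graph analytics
    (fixed points, elementary cycles, risk-zone classification), and a
    continuous hybrid Petri-net engine with mass-action kinetics.
    Ships the estrogen-receptor-alpha breast-cancer regulatory network
    (IGF-1R/EGFR, ER-alpha, BRCA1, p53, Mdm2) as a fully reproducible
    case study, together with synthetic network generators so every
    analysis stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
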