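Package: crdtiming
Title: Collective Risk Dilemmas with Timing Uncertainty
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying timing uncertainty in collective risk dilemmas
    (threshold public goods games): exact mechanics of the multi-round game with
    geometrically distributed ending rounds, a five-strategy behavioral model
    (unconditional givers, compensators and group reciprocators), stochastic
    evolutionary dynamics in finite populations under the pairwise-comparison
    (Fermi) rule with a small-mutation-limit stationary analysis, the analysis
    stages for behavioral-experiment decision tables (per-round means, group
    success rates, fairness and half-game splits, conditional-response tables
    with weighted regression, behavioral profile classification), and a seeded
    synthetic-cohort generator with planted ground truth for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
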