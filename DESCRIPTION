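Package: pruCEA
Title: Markov Cohort Cost-Utility Model of Prucalopride for
    Laxative-Refractory Chronic Constipation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A nine-state Markov cohort model comparing prucalopride with
    continued laxative treatment in adults with chronic constipation in whom
    laxatives fail to provide adequate relief, from the Dutch payer
    perspective. Implements the full decision-analytic pipeline: typed and
    validated model parameters with YAML configuration, monthly-cycle cohort
    simulation with a week-4 stopping rule, state-based costing (drugs,
    consultations, complications, transport, productivity losses), QALY
    accrual with annual discounting, incremental cost-effectiveness analysis,
    one-way and scenario sensitivity analyses, and probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves. A synthetic-data
    module generates trial-layer responder data and resource-use panels for
    validation without external inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
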