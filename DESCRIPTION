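Package: phasepk
Title: Phase 1 Pharmacokinetic, Receptor-Occupancy and Trial-Logic Analysis
    for Therapeutic Antibodies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for first-in-human dose-escalation
    studies of monoclonal antibodies: closed-form two-compartment IV-infusion
    kinetics with dose superposition, noncompartmental analysis (linear-up
    log-down AUC, exhaustive terminal-slope selection), power-model dose
    proportionality, a two-stage population PK estimator with an allometric
    body-weight covariate on clearance, virtual-population steady-state
    trough simulation with receptor-occupancy fold-margins, PD-1
    receptor-occupancy analytics, and trial-logic computations (3+3 and
    modified 6+6 dose-escalation rules, treatment-emergent adverse-event
    tables, immune-related RECIST confirmed-response tabulation). A seeded
    synthetic-trial generator emulates all four data streams so every stage
    is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
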