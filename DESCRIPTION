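Package: costkit
Title: Micro-Costing and Scale-Up Scenario Analysis for Health Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Phase-wise micro-costing of health interventions delivered in
    routine clinics: validated cost ledgers read from CSV or JSON, capital
    annualization with an annuity factor at a configurable discount rate,
    opportunity-cost valuation of staff time, apportionment of shared
    resources, per-patient unit-cost decomposition with proportional
    breakdowns, one-way deterministic sensitivity analysis with tornado
    ranking, scale-up scenario models (group counseling, bulk procurement,
    integrated training, cumulative), and a multi-year budget-impact
    projection with discounting. Ships a built-in ledger for a tobacco
    cessation package costed at two Indian noncommunicable-disease clinics,
    plus a synthetic-ledger generator with analytically known ground truth
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
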