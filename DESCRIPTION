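Package: msucost
Title: Cost-Consequence Analysis of Mobile Stroke Units Versus Standard Transport
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-consequence model comparing a Mobile
    Stroke Unit (MSU) with standard prehospital transport (ST) for suspected
    stroke. Provides a generic probability-tree engine with exact expected-cost
    roll-back and a path-enumeration oracle, the parameterized MSU/ST strategy
    model (annual totals, incremental cost, transfers and emergency-department
    encounters averted, ED-inclusion scenario), one-way deterministic
    sensitivity analysis with tornado ranking and threshold (break-even)
    search, seeded probabilistic sensitivity analysis with beta/gamma
    distribution assignment and a cost acceptability curve, and a synthetic
    patient-cohort simulator with conditional-probability estimation for
    parameter-recovery validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
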