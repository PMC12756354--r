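Package: pdcba
Title: Cost-Benefit Analysis of AI-Assisted MRI Triage for Parkinson's
    Disease Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-benefit model comparing an AI-assisted
    MRI triage pathway for suspected Parkinson's disease against a
    conventional PET-first diagnostic pathway. Evaluates the eighteen
    marginal benefit and marginal cost terms of the one-year cohort model,
    aggregates them into net benefit and benefit-cost ratio, and provides
    scenario machinery: adoption-rate sweeps, one-way deterministic
    sensitivity analysis, a closed-form break-even AI price, and a
    configurable multi-year projection. A patient-level Monte-Carlo
    microsimulator samples individual diagnostic trajectories and serves
    as an independent stochastic cross-check of every closed-form
    aggregate. Ships parameter sets for a South Korean societal-perspective
    analysis and a United States healthcare-system-perspective analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
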