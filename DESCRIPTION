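Package: cholecea
Title: Cost-Utility Analysis of Cholecystectomy Versus Conservative
    Management for Symptomatic Gallstones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Trial-based and model-based economic evaluation of
    laparoscopic cholecystectomy against conservative management for
    uncomplicated symptomatic gallstones, from the UK NHS perspective.
    Provides a seeded synthetic-trial generator emulating a two-arm
    multicentre randomised trial with 24-month follow-up; discounted
    QALY (trapezoidal area-under-curve) and resource-use costing;
    adjusted incremental costs and QALYs via generalised linear models
    with chained-equations multiple imputation and stratified
    non-parametric bootstrap; ICER, cost-effectiveness acceptability
    curves and net monetary benefit; and a monthly-cycle Markov cohort
    model with tunnel states, life-table mortality, probabilistic
    sensitivity analysis and a microsimulation validation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
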