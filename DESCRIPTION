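Package: ckdmarkov
Title: Population-Level Markov Modelling of Chronic Kidney Disease Burden
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic 16-state Markov cohort model of chronic kidney
    disease (CKD) progression in the UK adult population, projected over a
    10-year horizon in quarterly cycles. Provides transition-probability
    machinery (annual-to-quarterly rate conversion, life-table mortality with
    per-state relative risks), declarative intervention specifications
    (earlier diagnosis, improved hypertension management, SGLT-2 inhibitor
    uptake, pre-emptive transplantation), a capacity-constrained scenario,
    discounted cost and QALY accrual with incremental cost-effectiveness
    ratios, one-way tornado sensitivity analysis, a synthetic parameter-set
    generator, and an individual-level microsimulation used as a validation
    oracle for the cohort projection.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
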