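Package: hboccea
Title: Cost-Effectiveness Modelling of BRCA1/2 Testing and Risk-Reducing
    Strategies for Hereditary Breast and Ovarian Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov cohort model comparing BRCA1/2 genetic counselling,
    testing and preventive strategies (intensified surveillance,
    risk-reducing mastectomy and/or salpingo-oophorectomy) against standard
    care for 30-year-old women at high risk of hereditary breast and
    ovarian cancer, from a public-payer perspective. Provides a typed,
    validated parameter set covering transition probabilities, health-state
    utilities and costs; a tunnel-state Markov engine with discounted cost,
    QALY and life-year accumulation; incremental cost-effectiveness
    analysis; one-way deterministic (tornado) and probabilistic (Monte
    Carlo, CEAC, INMB) sensitivity analyses; and a synthetic time-to-event
    registry generator with Kaplan-Meier re-derivation of annual transition
    probabilities for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
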