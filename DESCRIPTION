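Package: markovcea
Title: Markov Cohort Cost-Effectiveness Modelling of Health Promotion for
    Older People
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic five-state Markov cohort model for the long-term
    cost-utility analysis of health-promoting interventions delivered to
    community-dwelling older people. Dependency states (mild, moderate,
    severe, total dependency and death) carry per-state health-related
    quality-of-life weights and annual societal costs; annual transition
    matrices are validated, cohorts are propagated over yearly cycles, and
    discounted quality-adjusted life years (QALYs) and costs are accumulated.
    Intervention effects are derived as relative risks from one-year trial
    transition counts, intervention costs from itemised cost sheets, and
    scenarios (one-time first-year effect, yearly booster sessions,
    deterministic sensitivity variants) are compared incrementally against a
    no-intervention comparator. A synthetic-trial generator supports
    stochastic validation of effect estimation without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
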