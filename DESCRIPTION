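Package: stressecon
Title: Trial-Based Health-Economic Evaluation of Digital Stress-Management
    Interventions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for trial-based economic evaluation
    of digital (internet-based) stress-management interventions in employees.
    Covers TiC-P-style resource-use costing under societal and employer
    perspectives (human capital, Osterhaus and proxy good methods), derivation
    of symptom-free status from PSS-10 scores and of quality-adjusted life
    years by area under the utility curve, multiple imputation by chained
    equations with predictive mean matching and Rubin's-rules pooling,
    bootstrapped seemingly-unrelated-regression cost-effectiveness and
    cost-utility analysis with bias-corrected and accelerated intervals,
    cost-effectiveness planes and acceptability curves, net-benefit regression
    moderation, employer cost-benefit analysis (net benefit, return on
    investment, benefit-cost ratio, probability of positive return), and the
    standard sensitivity analyses (winsorized costs, alternative intervention
    price, alternative utility instrument). A seeded synthetic-trial generator
    with a missing-at-random dropout mechanism emulates the two-arm
    randomized-trial structure the analysis assumes, so the whole pipeline is
    testable without access to participant-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    boot,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
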