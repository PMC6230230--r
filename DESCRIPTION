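Package: ckdmicrosim
Title: Microsimulation Models of Chronic Kidney Disease Progression for
    Cost-Effectiveness Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Individual-level state-transition (microsimulation) models of
    chronic kidney disease progression for health-economic evaluation.
    Implements a kidney function-based model that tracks a continuously
    declining estimated glomerular filtration rate (eGFR) with per-patient
    log-normal decline slopes, a disease grade-based model over the discrete
    KDIGO CKD grades, and a translation step that calibrates the grade-based
    model's per-grade transition probabilities from simulated kidney-function
    trajectories so the two model families can be compared under identical
    conditions. Provides discounted quality-adjusted life-years and costs,
    Kaplan-Meier renal survival, cost-effectiveness threshold statistics for
    intervention pricing, and one-way and probabilistic sensitivity analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
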