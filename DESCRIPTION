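Package: pd1cea
Title: Markov Cohort Cost-Effectiveness Analysis of PD-1 Inhibitor Regimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for trial-based cost-effectiveness analysis of
    first-line PD-1 inhibitor regimens in advanced non-squamous non-small cell
    lung cancer: reconstruction of pseudo individual-patient data from
    digitized Kaplan-Meier curves and numbers-at-risk tables (Guyot method),
    parametric survival extrapolation with AIC/BIC model selection, a
    three-state (progression-free / progressive disease / death) Markov cohort
    model with 3-week cycles and discounted cost and QALY accrual, incremental
    cost-effectiveness and dominance analysis, one-way (tornado) sensitivity
    analysis, and probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves. A synthetic-trial module generates survival evidence
    with known ground truth so every stage is testable without figure
    digitization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    flexsurv,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
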