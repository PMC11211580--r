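Package: psmcea
Title: Partitioned-Survival Cost-Effectiveness Modelling for Second-Line
    NSCLC Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Cost-effectiveness analysis of sotorasib versus docetaxel for
    KRAS G12C-mutated non-small cell lung cancer, built as a reusable,
    tested pipeline: least-squares fitting of seven parametric survival
    families to digitized Kaplan-Meier coordinates with AIC model
    selection, a three-state (progression-free, progressed, dead)
    partitioned-survival cohort model with discounted cost and QALY
    accumulation, ICER and willingness-to-pay decision rules, one-way
    (tornado) and probabilistic sensitivity analyses with
    cost-effectiveness acceptability curves, and a synthetic-data
    generator calibrated to published trial summaries so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    flexsurv,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
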