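Package: gdmbalance
Title: Clinical-Microbiome Risk Modelling for Gestational Diabetes with
    Log-Ratio Balance Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and internally validating gestational
    diabetes mellitus (GDM) risk models that combine routine clinical
    predictors with a compositional log-ratio "micro-balance" feature
    derived from genus-level gut microbiome abundance tables. Provides
    OGTT-derived glycemic indices (trapezoidal AUC, incremental AUC,
    glucose excursions, IADPSG classification), gestational weight-gain
    categorisation, genus-level abundance processing (normalisation,
    genus collapse with family proxies, prevalence/abundance filtering,
    Chao1 richness, Firmicutes/Bacteroidetes ratio, a rank-based
    differential screen), maximum-likelihood logistic model fitting,
    bootstrap optimism-corrected discrimination and calibration,
    DeLong confidence intervals for the AUC, decision-curve analysis
    with case-control prevalence adjustment, a points-based nomogram,
    two-group comparison statistics, and a seeded synthetic cohort
    generator so the full pipeline is testable without access to
    participant-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
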