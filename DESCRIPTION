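Package: faersignal
Title: Pharmacovigilance Signal Detection and Time-to-Onset Analysis for
    FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for pharmacovigilance analysis of
    spontaneous adverse-event reports in the FDA Adverse Event Reporting
    System (FAERS) quarterly ASCII format: parsing and key-based
    deduplication of the DEMO/DRUG/REAC/OUTC/THER tables, suspect-drug
    matching by synonym list, disproportionality signal detection with the
    reporting odds ratio (ROR) and proportional reporting ratio (PRR),
    sex-stratified signals with Benjamini-Hochberg false-discovery-rate
    control and volcano-plot coordinates, FDA seriousness outcome
    classification and clinical-characteristics summaries, and
    time-to-onset analysis with Kaplan-Meier estimation, parametric
    Weibull/log-normal/log-logistic model fitting, AIC/BIC model selection
    and hazard-regime classification.  A built-in synthetic FAERS-like
    data generator with known statistical structure makes every stage
    testable without access to the real database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
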