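Package: pvscreen
Title: Multi-Source Pharmacovigilance Signal Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects adverse drug reaction (ADR) signals by combining three
    real-world evidence streams: relative-risk screening of drug-ADR pairs in
    a drug-registry cohort, exclusion of pairs already documented in drug
    labels, external validation by disproportionality analysis (proportional
    reporting ratio, reporting odds ratio, and the Bayesian confidence
    propagation neural network information component, each with a false
    discovery rate decision) on spontaneous-report data, and a supplementary
    laboratory-abnormality screen on electronic-health-record style data.
    Final signals are the intersection of registry-novel and
    spontaneous-report-significant pairs. Ships a synthetic-data module that
    generates registry, spontaneous-report and laboratory datasets with known
    embedded signals for calibration and end-to-end testing.
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
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
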