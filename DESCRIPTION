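Package: dredtt
Title: Drug-Related Emergency Department Visit Trigger Tool
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screening engine for detecting adverse-drug-event (ADE) related
    emergency department (ED) visits with a configurable 28-rule trigger tool
    (DrEDTT), together with the validation machinery used to characterise such
    tools: WHO-UMC causality-based case adjudication, stratified review
    sampling, positive predictive value, sensitivity and specificity with
    binomial confidence intervals, and a synthetic multi-center ED cohort
    generator with gold-standard labels so every stage can be exercised
    without real patient data. Cohorts are plain tibbles in a fixed flat-file
    dialect (CSV or JSON-lines); results carry broom-style tidy() and
    glance() methods and ggplot2 autoplot() displays.
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
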