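Package: tviprofiles
Title: Triple Variable Index Profiles from Intraoperative Monitoring Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds the Triple Variable Index (TVI), a composite intraoperative
    score summing population z-scores of mean arterial pressure (MAP),
    bispectral index (BIS), and total minimum alveolar concentration (MAC)
    within non-overlapping five-timepoint windows. Provides artifact
    filtering, MAC summation across inhaled agents, windowed TVI profile
    assembly, k-means discovery of elevated/mixed/depressed expression
    patterns, intraoperative hypotension and triple-low-state detection,
    mortality-window classification and per-cluster characterization,
    bootstrap median confidence intervals, and a bootstrap ROC comparison of
    median-TVI versus cumulative triple-low exposure as 30-day mortality
    predictors. Includes a seeded synthetic intraoperative cohort generator
    so the full pipeline is testable without protected health records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
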