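Package: survtrack
Title: Follow-Up Form Harmonization and Kaplan-Meier Survival Reporting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for reusing routine clinical follow-up documentation for
    survival analysis. Parses generic follow-up forms in a CDISC-ODM-style XML
    dialect, harmonizes department-specific status vocabularies to overall- and
    event-free-survival event indicators, deduplicates multi-form patients and
    builds analysis-ready survival records. Provides a from-scratch
    Kaplan-Meier product-limit estimator with Greenwood confidence intervals,
    median survival, numbers at risk and the log-rank test, plus follow-up
    data-quality reporting (item and form completeness, person-time
    completeness) and a synthetic cohort simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    xml2,
    jsonlite,
    MASS,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    survival,
    yaml,
    optparse
Config/testthat/edition: 3
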