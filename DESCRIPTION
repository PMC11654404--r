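Package: palliaudit
Title: Clinical Audit of Palliative Chemotherapy Claims Against
    Treatment Guidelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A rule engine and reporting pipeline for auditing health
    insurance claims filed under a catch-all "palliative chemotherapy -
    unlisted regimen" benefits package for breast cancer. Each claim's
    package selection and treatment are classified as appropriate,
    inappropriate, or cannot-assess with an explicit reason code and
    evidence trail, following a guideline-derived decision sequence
    (tissue diagnosis, documented metastasis or the surgery-to-chemotherapy
    date gap, and the guideline role of the administered regimen).
    Includes documentation-availability cataloguing, cohort summaries by
    hospital sector, claims-history metrics, a configurable drug-role
    catalog, and a seeded synthetic claims-cohort generator so the whole
    pipeline runs without access to confidential scheme data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
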