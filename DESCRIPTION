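Package: temporeg
Title: Temporal Regularity of Primary Care Visits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying the temporal regularity of primary care
    visits in HMO-style electronic health record extracts. Builds analytic
    cohorts of chronic-disease patients from delimited demographic, visit,
    diagnosis, laboratory and procedure tables using ICD code-list
    phenotyping; computes the coefficient of variation of inter-visit
    intervals as a patient-level regularity statistic and dichotomizes it
    into a least-regular group; fits bivariate and fully adjusted logistic
    models of least-regular care; and profiles clinics with case-mix
    adjusted observed/expected ratios. Includes a seeded synthetic cohort
    generator with known ground-truth effects so the whole pipeline is
    testable without access to proprietary claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
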