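Package: natriuria
Title: Spot-Urine Estimation of 24-Hour Urinary Sodium Excretion in CKD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate 24-hour urinary sodium excretion from spot
    urine samples with the Kawasaki, Tanaka and INTERSALT prediction
    equations, and to validate those estimates against measured 24-hour
    collections in chronic kidney disease (CKD) cohorts. Implements the
    study-protocol preprocessing of timed urine collections (validity
    screening, correction to 24 hours), agreement and diagnostic statistics
    (Spearman rank correlation, Fisher-Z comparison of correlations,
    Bland-Altman limits of agreement, +/-30 percent precision,
    sensitivity/specificity/PPV/NPV at guideline sodium thresholds), a
    seedable synthetic CKD-cohort generator with a Gaussian-copula link
    between spot concentrations and daily excretion, and an end-to-end
    analysis pipeline producing tidy report tables.
License: MIT
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
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
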