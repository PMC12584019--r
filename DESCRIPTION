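Package: clinstage
Title: ROC-Based Functional Staging of ClinFIT Total Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives functional staging cutoff scores for the Clinical
    Functioning Information Tool (ClinFIT) total raw score (0-300) against
    rehabilitation intensity measured by the Therapy Disciplines domain of
    the Rehabilitation Complexity Scale v2. Implements the stepwise ROC
    procedure (Youden-optimal cutoffs with sequential exclusion of
    higher-intensity patients), retention and merge rules for candidate
    cutoffs, subgroup re-derivation by sex, age band and diagnosis, pre/post
    paired effect-size statistics, a synthetic-cohort generator with
    plantable intensity thresholds, and exact confusion-matrix fixture
    construction for validating the procedure against published staging
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
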