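Package: dkafluids
Title: Physicochemical Acid-Base Analysis of Fluid Therapy in Diabetic
    Ketoacidosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative acid-base analysis of intravenous fluid therapy in
    the first six hours of diabetic ketoacidosis (DKA). Implements the Stewart
    (Figge-Fencl) strong ion gap, base-excess chloride (Na - Cl - 32 mmol/L)
    and Van Slyke standard base excess; a fluid composition registry with
    electrolyte mass-balance accounting and chloride-rich versus chloride
    non-rich regimen classification; cohort ingestion with inclusion filters
    and derived six-hour delta columns; the normality-gated two-group
    comparison battery, Pearson correlation and multivariate linear regression
    on ICU length of stay, and two-sample t-test power; and a reproducible
    synthetic two-arm DKA cohort generator for end-to-end testing when no
    patient data are available.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lmtest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
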