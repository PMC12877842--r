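Package: rplphewas
Title: Case-Control Phenome-Wide Association Analysis of Recurrent
    Pregnancy Loss from Electronic Health Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering diagnoses associated with
    recurrent pregnancy loss (RPL) in observational health records. Builds
    RPL case and live-birth control cohorts from OMOP-style person,
    condition and visit tables, aggregates windowed ICD diagnoses to
    Phecodes, and tests each candidate diagnosis with crude logistic and
    confounder-adjusted additive (GAM) models with maternal age entered as
    a spline plus race and ethnicity, applying Benjamini-Hochberg false
    discovery control. Includes age-stratified effect-heterogeneity
    z-tests, a healthcare-utilization sensitivity analysis, cross-center
    concordance classification, UMAP embedding of non-pregnancy diagnosis
    profiles, a next-pregnancy outcome analysis, and a two-center
    synthetic EHR generator with planted odds ratios so every stage is
    testable without access to protected patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    uwot,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
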