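Package: turnerscreen
Title: Family-Adjusted Short-Stature Screening for Turner Syndrome
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating short-stature screening in Turner syndrome
    against family height expectations. Provides an LMS-method growth-reference
    engine (height-for-age and birthweight-for-gestation standard deviation
    scores, with exact inverse transforms), mid-parental height and lower
    parental target range computation honouring measured versus reported
    parental height provenance, population- and family-referenced
    classification with age-stratified sensitivity tables, birthweight cut-off
    sensitivities, the crude-screening predictive-value calculation, and a
    seeded synthetic Turner-cohort generator calibrated to a published clinic
    audit so the full pipeline runs and is tested without access to case-note
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
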