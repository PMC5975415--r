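Package: miascreen
Title: Multivariate Index Assay Triage of Ovarian Masses and Its
    Diagnostic-Accuracy Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a software-independent modified multivariate index
    assay (MIA) for preoperative triage of ovarian masses: five serum
    biomarkers (CA 125, beta-2 microglobulin, transferrin, apolipoprotein A1
    and prealbumin) are each called positive against laboratory reference
    ranges and a mass is flagged high risk when at least three of the five
    calls are positive. The package couples the rule with the complete
    evaluation machinery of a diagnostic-accuracy study: confusion tables
    against the histopathology gold standard, sensitivity, specificity and
    predictive-value reports, the exact binomial McNemar test, Pearson
    chi-square and two-sided Fisher exact risk-factor association with the
    expected-count selection rule, reconstruction of integer confusion cells
    from published summary statistics, FIGO-stage-stratified analyses, a
    class-conditional synthetic cohort generator, and a one-command reporting
    pipeline that renders the full set of study tables from a per-patient
    cohort CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
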