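Package: radbayes
Title: Cohort-Predictive Term Mining from Radiology Reports with Naive Bayes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts cohort-predictive terms from free-text radiology
    reports of two genotype cohorts (e.g. KRAS-mutant versus wild-type
    colorectal cancer) by document-frequency analysis. Reports are
    tokenized, Porter-stemmed and negation-tagged with a proximity
    window; per-term naive Bayes posteriors are computed from smoothed
    per-cohort document frequencies, predictor term sets are selected by
    posterior threshold and absolute posterior difference, and predictor
    groups are evaluated with an exact Wilcoxon signed-rank test. A
    synthetic two-cohort corpus generator with planted marker terms and
    analytic ground-truth posteriors supports end-to-end validation and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
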