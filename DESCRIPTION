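Package: tnmstager
Title: Rule-Based TNM Staging and Evaluation for Lung Cancer Radiology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic AJCC 8th-edition TNM staging engine for
    non-small cell lung cancer built on structured radiology-report
    findings, together with the evaluation toolkit needed to audit such
    an engine: a bilingual (Chinese/English) lexicon-based extractor with
    strict and lenient metastasis interpretation strategies, clinical
    stage grouping with rule-firing traces, a clinical-impact error
    taxonomy, paired multi-class model comparison (Bowker symmetry test,
    Cohen omega), Wilson confidence intervals, macro precision/recall/F1,
    Cohen kappa, and a label-first synthetic cohort generator that renders
    pseudo-reports for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
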