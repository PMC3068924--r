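Package: caerus
Title: Domain-Interaction Network Signatures for Cancer Outcome Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores proteins by the domain-domain interaction (DDI) structure
    of their protein-protein interaction (PPI) neighborhood, optionally
    weighted by somatic mutation counts within domains, and selects
    high-scoring proteins as gene signatures. Patient expression profiles are
    converted into signature-neighborhood co-expression-difference features
    and classified into good versus poor outcome with a 20-bin naive Bayes
    classifier under nested cross-validation. Includes a seeded simulator of
    interactome bundles and patient cohorts with planted singlish-interface
    hub signatures for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
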