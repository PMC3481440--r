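Package: chemoclust
Title: Semi-Supervised Survival Clustering of Multi-Omics Chemotherapy
    Response Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies molecular classifications associated with
    chemotherapy response in multi-omics cancer cohorts while reducing
    confounding (batch, age, tumor stage) and suppression (mixed treatment)
    effects. Implements location/scale batch-effect adjustment for log2
    expression and bounded methylation beta values, rule-based selection of
    uniformly treated samples, progression-free-survival-driven
    semi-supervised clustering via a ternary F-score discretization of copy
    number and methylation status, Jaccard-distance complete-linkage
    clustering into poor and good prognosis tumors, weighted k-nearest
    neighbor classification of held-out samples, and differential expression
    calling. A synthetic cohort generator with planted copy-number and
    methylation subtypes makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    withr
Config/testthat/edition: 3
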