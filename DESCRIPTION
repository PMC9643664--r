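Package: fibrotype
Title: Endotype Discovery from Multi-Cohort Blood Transcriptomes in Pulmonary Fibrosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering and validating molecular endotypes of
    idiopathic pulmonary fibrosis from pooled blood gene-expression cohorts. Implements
    control-anchored ComBat co-normalisation of multiple cohorts (batch location/scale
    effects estimated from healthy controls only, with empirical-Bayes shrinkage),
    consensus clustering with two algorithms and five validity indices summarised as an
    optimality map over cluster number and gene-subset size, agreement-based core
    assignments with unclustered calls, a greedy forward-selected gene-expression cluster
    classifier, up/down-signature risk scoring, and a survival and clinical-trait
    statistics layer (Kaplan-Meier, log-rank, Cox proportional hazards, Harrell's
    concordance index, nested likelihood-ratio tests, GAP index, hypergeometric
    over-representation). Includes a synthetic multi-cohort generator with known ground
    truth so the full discovery and validation workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    cluster,
    survival,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml
Config/testthat/edition: 3
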