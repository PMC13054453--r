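Package: sdrnet
Title: Disproportionality Signal Detection and Co-Reporting Networks for
    Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection from individual
    case safety report (ICSR) databases. Implements the Bayesian information
    component (IC) with exact gamma-posterior credibility bounds, the
    IC025 > 0 signal criterion, and four sensitivity analyses (reporter-type
    restriction, ATC level-3 background, Mantel-Haenszel stratification by
    sex and age, broadened case definition); case-feature summaries and
    cross-analysis consistency flags; event-event disproportionality with
    Ising-model and positive pointwise mutual information (PPMI) symptom
    networks and community detection; drug-target aggregation; and a
    synthetic ICSR generator with planted associations, confounding and
    symptom clusters for validating every stage against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    glmnet,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
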