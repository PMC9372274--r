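Package: phenoclust
Title: Ontology-Based Deep Phenotyping, Patient Clustering and Survival
    Analysis for Congenital Heart Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for stratifying patient cohorts annotated with Human
    Phenotype Ontology (HPO) terms. Parses OBO ontologies into a directed
    acyclic graph, computes cohort-frequency information content and Resnik
    term similarity, aggregates term similarities into best-match-average
    patient similarity, clusters the derived distance matrix with
    complete-linkage agglomeration, characterizes the resulting phenotype
    clusters with categorical and continuous group tests, and compares
    cluster outcomes with Kaplan-Meier curves, log-rank tests and Cox
    proportional-hazards regression. Ships a synthetic-cohort simulator with
    planted phenotype clusters and proportional-hazards survival so the full
    pipeline is testable without access to hospital records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
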