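Package: prostaging
Title: Rule-Based AJCC Staging and Validation of Prostatectomy Pathology Data
Version: 0.1.0
Authors@R:
    person("Pathology", "Informatics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An automated American Joint Committee on Cancer (AJCC, 8th
    edition) staging pipeline for structured radical-prostatectomy pathology
    data. Provides a prioritized rule engine with explicit missing-data
    semantics and M-stage imputation, consistency validation of T/N stage
    against invasion and lymph-node findings and of Gleason scores against
    WHO/ISUP Grade Groups, an in-memory property-graph representation with
    GraphML/Cypher/JSON export, a deterministic offline extractor for
    synoptic, narrative and tabulated report text, a seeded synthetic report
    generator with targeted inconsistency injection, and evaluation
    statistics (micro/macro precision, recall and F1, Wilson score intervals,
    Fisher's exact and Pearson chi-squared tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
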