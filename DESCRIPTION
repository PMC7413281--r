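Package: mkgfwa
Title: Medical Knowledge Graph Screening of Insurance Claims for Fraud,
    Waste, and Abuse
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds a typed medical knowledge graph (diseases, drugs, ATC
    classes, examinations) from tabular node/edge data and from
    drug-label-like text via rule and pattern based extraction; normalizes
    free-text claim terms onto graph entities with a multilevel fuzzy
    string matcher (character, radical, and pronunciation levels) combined
    with semantic-unit decomposition; and screens insurance claims for
    three suspicious scenarios (fraud diagnosis, excess prescription,
    irrational prescription) by bounded multihop graph reasoning, emitting
    evidence paths as explanations. Includes seeded generators for toy
    knowledge graphs and claim batches with planted events so the whole
    pipeline is testable without external data.
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
    igraph,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
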