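Package: OntoKGE
Title: Multi-Ontology Knowledge Graphs and Embedding-Based Gene-Disease Link Prediction
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joins a gene ontology and a disease ontology into a single
    knowledge graph via corpus-derived "bridge" edges and predicts unseen
    gene-disease associations with knowledge-graph-embedding (KGE) models.
    Provides OBO and edge-list ingestion of subclass hierarchies, sentence-level
    gene-disease corpus handling (label binarization, balancing, negative pair
    sampling, prompt generation), frequency-based bridge selection with CURIE
    mapping, seven KGE scoring families (UM, TorusE, RotatE, PairRE, ComplEx,
    SimplE, KG2E) trained by seeded mini-batch SGD with negative sampling, and
    rank-based link-prediction evaluation (MR, MRR, Hits@k) under raw and
    filtered protocols. Seeded synthetic generators for ontologies, corpora and
    planted-block association graphs make the whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
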