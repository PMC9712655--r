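Package: steroqsar
Title: Structure-Based Profiling and Imbalance-Aware QSAR for Steroidogenesis-Active Chemicals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to profile and predict chemicals that increase estradiol or
    progesterone synthesis in the H295R steroidogenesis assay. Provides SMILES
    structure curation (salt stripping, metal and mixture rejection), 1D/2D
    molecular descriptor computation with variance- and correlation-based
    selection, self-organizing-map clustering with per-cluster activity
    enrichment, MACCS/Tanimoto similarity and applicability-domain scoring,
    chemotype chi-squared enrichment with co-occurrence networks, and
    imbalance-aware random-forest QSAR classification with GHOST decision
    threshold shifting and confidence-tiered prediction. Includes a seeded
    synthetic chemical library generator with planted substructure-activity
    signal so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    randomForest,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
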