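Package: rpiboost
Title: Sequence-Based Prediction of RNA-Protein Interactions with
    Gradient-Boosted Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts RNA-protein interactions from sequence alone using a
    reduced amino-acid alphabet derived from structure-based interaction
    propensities and a five-residue minimum-structural-unit k-mer encoding.
    Provides tools to parse RNA-protein complex structures (PDB/mmCIF),
    detect binding interfaces by distance cutoffs, compute amino-acid
    interaction propensities, build deduplicated positive and
    similarity-filtered negative training corpora, encode sequence pairs as
    2048-dimensional normalized k-mer vectors, and train and evaluate an
    XGBoost binary classifier under stratified nested cross-validation.
    Includes generators for synthetic toy complexes and motif-planted
    sequence corpora so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    Matrix,
    xgboost,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
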