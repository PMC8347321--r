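Package: cypsubstrate
Title: Substrate Classification Models for Human Cytochrome P450 Isozymes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curation-to-prediction pipeline for classifying small organic
    molecules as substrates or non-substrates of nine human cytochrome P450
    (CYP) isozymes (1A2, 2A6, 2B6, 2C8, 2C9, 2C19, 2D6, 2E1, 3A4). Provides
    chemical structure standardization and label-conflict-aware deduplication,
    four molecular feature families (MACCS keys, Morgan fingerprints,
    physicochemical 2D descriptors, substructure embeddings), per-isozyme
    random forest and support vector machine classifiers selected by grid
    search within stratified five-fold cross-validation, abstaining consensus
    models (soft, hard and max voting), applicability-domain reporting based
    on nearest-training-neighbor Tanimoto similarity, chemical-space coverage
    analysis, and a synthetic fixture generator for offline testing. Structure
    handling is delegated to RDKit through the system 'python' interpreter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    pROC,
    ranger,
    stats,
    utils
SystemRequirements: python (>= 3.8) with the rdkit package on the PATH
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
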