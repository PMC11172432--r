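Package: dfppi
Title: Protein-Protein Interaction Prediction by Deep Feature Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequence-only prediction of protein-protein interactions by
    fusing handcrafted sequence descriptors (local descriptor
    composition/transition/distribution encoding, unit-circle F-vector,
    and an amphiphilic pseudo-amino-acid composition extended with
    tripeptide correlation terms) with learned amino-acid embeddings
    inside a two-channel multilayer perceptron. Includes a distributed
    memory paragraph-vector trainer for amino-acid embeddings, stratified
    cross-validation with the standard binary-classification metrics,
    positive-only threshold-accuracy area-under-curve evaluation, F1-based
    threshold selection, interaction-network edge reconstruction, and a
    reproducible synthetic benchmark generator with planted interaction
    motifs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
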