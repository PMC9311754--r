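Package: pssmLPP
Title: Sequence-Based Protein-Protein Interaction Prediction with
    Locality Preserving Projections and Rotation Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts protein-protein interactions from sequence alone.
    Each protein is represented by its position-specific scoring matrix
    (PSSM, the ASCII output of PSI-BLAST), condensed into a fixed-length
    evolutionary composition descriptor, embedded into a low-dimensional
    space with Locality Preserving Projections (a graph-Laplacian linear
    embedding solved as a generalized eigenproblem), and protein pairs are
    classified with a Rotation Forest ensemble of decision trees built on
    per-subset PCA rotations. Includes stratified cross-validation and
    independent-test evaluation (accuracy, precision, sensitivity, MCC,
    ROC/AUC), plus a synthetic benchmark generator that plants a tunable
    latent-similarity interaction signal so the whole pipeline can be
    exercised without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
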