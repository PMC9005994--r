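Package: m5Cpredict
Title: Sequence-Based Prediction of RNA 5-Methylcytosine Sites
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting 5-methylcytosine (m5C) modification sites
    in RNA from primary sequence. Fixed-length 41-nt windows centered on
    candidate cytosines are encoded into seven sequence feature families
    (sliding-window nucleotide composition, k-spaced nucleotide pairs,
    accumulated nucleotide frequency, nucleotide chemical properties,
    one-hot encoding, series-correlation pseudo dinucleotide composition,
    and k-mer word embeddings), ranked by Shapley-value, F-score or
    minimum-redundancy-maximum-relevance criteria, reduced by incremental
    cross-validated feature selection, and classified with gradient-boosted
    trees (with random-forest and support-vector-machine baselines).
    Includes a synthetic benchmark generator with planted positional signal
    for end-to-end validation, full evaluation metrics (ROC/PR curves,
    Matthews correlation, false omission rate, FPR-matched thresholds) and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    Matrix,
    xgboost,
    ranger,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
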