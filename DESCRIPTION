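Package: bleatr
Title: Lightweight Acoustic Feature Pipeline for Goat Vocalization
    Classification
Version: 0.1.0
Authors@R:
    person("bleatr", "developers", email = "bleatr@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for classifying caprine vocalizations from
    one-dimensional acoustic descriptors, designed for edge deployment on
    low-power farm hardware. Reads and standardizes WAV clips, extracts a
    156-descriptor feature vector (MFCC with first and second derivatives,
    spectral shape and contrast, spectral entropy and flatness, ecoacoustic
    complexity indices, and pYIN fundamental-frequency statistics), balances
    training data with SMOTE, trains tree ensembles and a compact multilayer
    perceptron, reports weighted multiclass metrics including Cohen's kappa,
    ranks features by permutation importance, and benchmarks inference
    latency and serialized model footprint. Includes a class-conditioned
    synthetic bleat generator so every stage is testable without a recorded
    corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    FNN,
    glmnet,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
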