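Package: ersnet
Title: Recurrent Ensemble Prediction of ER Retention Sequence Secretion Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Predicts whether a seven-residue C-terminal tail behaves as an
    endoplasmic-reticulum retention/retrieval sequence (ERS) that is secreted
    upon ER calcium depletion. An ensemble of independently seeded LSTM
    regressors is trained on tail/secretion-response pairs (one-hot encoded
    7x20 matrices) and scored by the ensemble mean. The package also provides
    proteome-wide C-terminal tail extraction from protein FASTA, permutation
    candidate generation from per-position high-frequency residue sets,
    PAM250 similarity scoring against a reference motif, position probability
    matrices (sequence-logo data), bootstrap ensemble-convergence analysis,
    10-fold cross-validation, and a seeded synthetic-data generator for
    benchmarking the full pipeline without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
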