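Package: bcnmf
Title: Similarity-Constrained Non-Negative Matrix Factorization for
    Drug-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts new therapeutic indications for existing drugs by
    completing a binary drug-disease association matrix with a low-rank
    non-negative factorization that is regularized both by Tikhonov
    (Frobenius) penalties on the factors and by constraints tying the
    factor Gram matrices to precomputed drug-drug and disease-disease
    similarity networks.  Provides the multiplicative-update optimizer,
    per-drug candidate ranking, a cross-validation harness reporting
    AUC, AUPR, accuracy, sensitivity, specificity, precision and F1,
    labeled-matrix input/output, a planted-structure synthetic benchmark
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
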