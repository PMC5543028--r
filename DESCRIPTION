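Package: adbench
Title: Benchmarking Applicability-Domain Measures for Classification Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A catalogue of applicability-domain (AD) measures for two-class
    classifiers on cheminformatics-style tabular data -- label-free novelty
    measures (the DA-index kappa/gamma/delta under Euclidean or Tanimoto
    distance, and the mean-cosine measure) and classifier-derived confidence
    measures (class-probability estimates, CLASS-LAG, ensemble standard
    deviation, PROB-STD, vote fraction, boosting margins, Platt-scaled SVM
    scores) -- together with the cross-validated benchmarking pipeline that
    ranks them by how well they separate reliable from unreliable predictions
    (signed-score ROC curves with closed-form AUC bounds, cumulative-accuracy
    and predictiveness curves, permutation significance tests, rank
    aggregation across data sets) and reject-option thresholding. Includes a
    synthetic-data generator emulating the statistical structure of molecular
    descriptor benchmark sets so the whole pipeline runs without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    e1071,
    nnet,
    randomForest,
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
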