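Package: minens
Title: Minimalist Ensemble Prediction of Protein Subcellular Localization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building minimalist ensemble predictors of protein
    subcellular localization from the categorical outputs of standalone
    prediction tools. Implements per-predictor contribution scores that
    reward correct minority predictions, correlation-based feature subset
    selection (CFS merit with symmetric uncertainty) with greedy backward
    stepwise search, meta-classifier ensemble schemes (accuracy-weighted
    voting, regularized LDA, categorical naive Bayes, CART decision trees,
    multinomial logistic regression), stratified cross-validated evaluation
    by overall accuracy and per-class Matthews correlation, and a synthetic
    prediction-table generator with controlled class priors, per-predictor
    accuracies and group-correlated errors for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    rpart,
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
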