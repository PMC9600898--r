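Package: copdgnn
Title: COPD Stage Classification with Radiomics Combination Vectors and an
    Auto-Metric Graph Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies chronic obstructive pulmonary disease (COPD) severity
    (four GOLD stages, III and IV merged) from tabular radiomics or CNN-derived
    feature tables. Builds a "combination vector" of K risk factors (ranked by
    univariate generalized-linear-model R-squared) and d node features (selected
    by the Lasso with 10-fold cross-validation), then classifies stages with an
    auto-metric graph neural network trained by episodic N-way-K-shot
    meta-learning: per-episode graphs over labelled support nodes and an unknown
    query node, a learned pairwise-metric edge weight matrix gated by a
    risk-factor edge constraint matrix. Includes a synthetic-cohort generator
    with correlated feature blocks and ordered class-mean shifts, six reference
    classifiers, stratified cross-validated model selection, multi-class
    one-vs-rest ROC AUC metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    glmnet,
    pROC,
    e1071,
    randomForest,
    nnet,
    MASS,
    xgboost,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
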