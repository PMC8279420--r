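Package: metabokit
Title: Tidy Statistical Workflows for Metabolomics and Proteomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable implementation of the standard statistical workflow
    for quantified metabolomics and proteomics experiments: paired target and
    features CSV input, zero/missing-value handling with a group-wise
    missingness filter and six imputation methods, six intensity normalization
    methods, multivariate group-dependent outlier detection in principal
    coordinate space, univariate and empirical-Bayes moderated tests with
    false discovery rate control, PCA, (sparse) partial least squares
    discriminant analysis with variable importance and cross-validation,
    k-means clustering with elbow selection, correlation and Gaussian
    graphical model networks, penalized logistic and random forest
    classification with honest train/test validation, odds ratios, and the
    rank product test. Includes a deterministic synthetic-data generator with
    known ground truth and a reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    limma,
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
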