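Package: ocgene
Title: One-Class Classification for Disease-Gene Prioritization from
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prioritizes candidate disease genes from a condition-labelled
    gene expression matrix using one-class classification. Builds a
    positive/unlabeled gene benchmark by differential expression
    (log fold change and Benjamini-Hochberg adjusted p-values), trains a
    nu-parameterized one-class support vector machine (and the equivalent
    support vector data description) with linear or radial basis function
    kernels via an in-package sequential-minimal-optimization dual solver,
    and evaluates with positive-unlabeled precision/recall estimators that
    do not require labelled negatives. Includes balanced binary-classifier
    baselines (SVM, k-nearest neighbours, decision tree), a synthetic
    expression-matrix generator with planted disease genes for validation,
    and a command-line interface covering the full experiment.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    class,
    rpart
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
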