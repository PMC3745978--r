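Package: abcfs
Title: Artificial Bee Colony Feature Selection with Support Vector
    Machine Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Wrapper feature selection for two-class tabular (medical)
    datasets. Candidate feature subsets are scored by a supervised
    clustering classifier whose class prototypes ("food sources") are
    trained with the artificial bee colony (ABC) metaheuristic on a
    stratified 75/25 split, averaged over repeated runs; subsets grow by
    sequential forward selection until the score declines. The reduced
    data are then classified with a linear support vector machine under
    stratified k-fold cross-validation, reporting accuracy, sensitivity,
    specificity and predictive values from the confusion matrix. Includes
    readers for UCI-style delimited files with per-class mode imputation,
    min-max scaling, a synthetic benchmark generator with known
    informative/noise structure, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
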