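Package: coexScreen
Title: Discriminative Gene Communities from Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies case/control-discriminative gene communities in bulk
    expression data. Builds a significance-filtered Pearson co-expression
    network, partitions it with ensemble Leiden community detection under
    stability, substantiality and non-fragmentation criteria with recursive,
    size-constrained subdivision, screens every community with a Random
    Forest classifier under repeated stratified cross-validation with Boruta
    shadow-feature selection nested in each fold, tests communities for
    annotation over-representation with the hypergeometric distribution, and
    explains retained classifiers with exact interventional Shapley values.
    Includes a synthetic-data generator with planted modules, class signal
    and batch effects for ground-truth validation, plus controls-anchored
    batch adjustment, log2 and quantile normalization preprocessing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
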