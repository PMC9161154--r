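Package: ensemblefs
Title: Ensemble Feature Selection for Two-Class Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ensemble biomarker discovery for two-class gene expression
    studies. Six independently implemented feature filters (Welch t-test,
    one- and two-dimensional information-theoretic filters, fast
    correlation-based filter, ReliefF, and minimum-redundancy
    maximum-relevance) are ranked inside repeated stratified
    cross-validation, redundancy-pruned by Spearman correlation, validated
    with random-forest classifiers (AUC, Matthews correlation coefficient),
    scored for selection stability with the Lustgarten measure, and
    aggregated into a consensus key-gene table with log2 fold changes and
    optional membrane/drug annotation and network hub ranking. Includes a
    seeded synthetic expression-data generator with known ground truth
    (mean-shift markers, correlated gene blocks, XOR-style interacting
    pairs, batch effects) so the whole pipeline is testable without any
    external download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    randomForest,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
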