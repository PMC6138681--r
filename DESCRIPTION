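Package: mircuits
Title: Integrative miRNA-mRNA Analysis of Hormone-Reverted Expression Circuits
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for identifying miRNA-gene regulatory
    circuits whose dysregulation after cardiac ischemia-reperfusion is reverted
    by thyroid hormone (T3) replacement. Implements delta-delta-Cq relative
    quantification of qPCR panel data with housekeeping normalization and exact
    nonparametric three-group testing; negative-binomial differential expression
    for small-RNA count matrices (median-of-ratios size factors, pooled
    method-of-moments dispersion with a fitted mean-dispersion trend, exact
    conditional test, Benjamini-Hochberg adjustment and fold/abundance/FDR
    filters); classification of three-group expression trajectories into
    reversal categories; crossing of reverted miRNAs against reverted genes
    through target-prediction tables restricted to anti-modulated couples;
    hypergeometric over-representation analysis; and assembly of
    score-thresholded interaction networks with hub and bridge identification.
    A synthetic-data generator with planted effects makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
biocViews: GeneExpression, DifferentialExpression, miRNA, NetworkInference,
    qPCR, Regression
RoxygenNote: 7.3.3
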