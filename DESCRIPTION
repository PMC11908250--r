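Package: momirf
Title: Multi-Omics Variable Selection with Multivariate Random Forests
    and Inverse Minimal Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Grows multivariate regression forests over paired omics
    matrices, assigns a maximal-splitting response variable (MSRV) to every
    node split, and scores predictors and responses with an inverse
    minimal depth (IMD) statistic. Cross-correlated features shared by two
    or more omics layers are selected with three alternative rules:
    standard-deviation filtering tuned by out-of-bag error, a
    zero-inflated two-component mixture model fitted by EM, and t-score
    thresholding of the IMD. Includes latent-factor and non-linear
    regression simulators with known truth for benchmarking, a
    precision-recall evaluation harness, and a multi-omics integration
    layer that ranks directional models by out-of-bag error.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'momirf-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'simulate.R'
    'forest.R'
    'oob.R'
    'imd.R'
    'selection.R'
    'multiomics.R'
    'evaluate.R'
    'io.R'
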