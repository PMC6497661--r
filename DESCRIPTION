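Package: morphoshift
Title: Adaptive-Zone Shift Detection and Macroevolution of 3D Landmark Shape
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative analysis of 3D geometric morphometric
    data on phylogenies. Reads, completes (reflected relabeling and iterative
    PCA imputation) and superimposes landmark/semilandmark configurations
    (generalized Procrustes analysis with Procrustes-distance sliding of
    semilandmarks), builds standard and phylogenetically corrected principal
    component morphospaces with parallel-analysis axis retention, computes
    disparity-through-time curves and the morphological disparity index with
    a Brownian-motion simulation null, contrasts morphology dendrograms with
    the phylogeny via tanglegram tip displacement, detects adaptive-zone
    shifts with a lasso-based multi-peak Ornstein-Uhlenbeck search scored by
    phylogenetic BIC with parametric-bootstrap support, and compares fully
    multivariate evolutionary models (BM, OU, early burst, multi-peak OU on
    stochastic character maps) by AICc. Includes a synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    glmnet,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), deSolve, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
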