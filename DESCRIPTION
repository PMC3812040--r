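Package: motilitykit
Title: In Vitro Motility Assay Analysis and Coupled-Myosin Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying actin filament sliding in the in vitro
    motility assay and for explaining condition-dependent motility with a
    stochastic model of mechanically coupled myosin motors. Includes a
    ground-truth mock-video generator, automated filament tracking with
    rectangle-equivalent length estimation, decision-tree-ensemble trace
    quality control, length-resolved motility features (sliding velocity,
    motile fraction, run and stop times) with bootstrap confidence bands,
    bootstrapped principal component analysis with hierarchical clustering
    and fold-change tests, and an exact Gillespie simulator of actin
    propulsion by strain-coupled myosins.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    randomForest,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
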