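Package: pcmap
Title: Partial Cross Mapping for Direct Causality in Nonlinear Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects causal links between variables of a nonlinear dynamical
    system from multivariate time series and distinguishes direct causation
    from indirect causation transmitted through mediating variables. Implements
    mutual cross mapping on delay-coordinate (shadow) manifolds with
    simplex-weighted nearest-neighbour estimates and optimal-delay scanning,
    and partial cross mapping, which conditions the cross-map association on
    nested cross-map estimates routed through candidate mediators. Includes
    automatic embedding-parameter selection (false nearest neighbours, delayed
    mutual information), coupled logistic-map benchmark generators with known
    ground-truth graphs, surrogate significance testing, network-scale
    inference, and ROC-based evaluation against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
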