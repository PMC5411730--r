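Package: stepstone
Title: Stepwise Adaptive Expansion of Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how complex metabolic innovations can evolve
    through series of single adaptive steps. Implements constraint-based
    modelling of metabolic networks (flux balance analysis, flux variability),
    curation of a merged host-plus-universal reaction pool (duplicate removal,
    elimination of energy-generating cycles, removal of unconditionally blocked
    reactions), screening of single-nutrient-swap environments for novel growth
    phenotypes, exact minimisation and exhaustive enumeration of minimal
    growth-enabling reaction additions by branch-and-bound over reaction
    indicator variables, classification of growth-promoting reaction pairs and
    stepping-stone reactions, and phylogenetic tests of contingent gene gain
    and co-gain on presence/absence profiles over a species tree (weighted
    Sankoff parsimony with delayed-transformation resolution). A synthetic-data
    generator provides toy networks with planted innovation pathways and
    simulated gene histories with planted contingency for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
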