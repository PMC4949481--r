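Package: chassisDesign
Title: Growth-Coupled Strain Design for Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Constraint-based design of microbial production strains. Provides
    an in-memory stoichiometric model class with gene-reaction rules and
    reaction knockouts; flux balance analysis (FBA), two-stage lexicographic
    optimization, parsimonious FBA and flux variability analysis on top of a
    solver-agnostic linear-programming contract with a built-in bounded-variable
    simplex backend; model curation (duplicate merging, secretion blocking,
    blocked-reaction removal) and producer-model construction from heterologous
    pathway tables; exhaustive knockout enumeration with a robust
    minimal-product-at-maximal-growth coupling criterion and yield filters; a
    metabolite-turnover-distance predictor of mutant flux phenotypes screened
    against a carbon-catabolite-repressed reference state; identification of
    product-essential reactions and minimal required fluxes as overexpression
    targets; and hierarchical clustering of products into modular chassis
    groups. Ships parametric synthetic model generators with planted couplings
    and brute-force oracles so every pipeline stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    xml2,
    yaml,
    ape,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
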