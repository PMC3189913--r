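Package: pantherin
Title: Morphometric and Cladistic Analysis of Pantherine Skulls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A workflow for diagnosing fossil pantherine cats from
    craniodental data: generalized Procrustes superimposition and
    thin-plate-spline decomposition of landmark shape into uniform and
    partial/relative warp components; maximum-parsimony inference on
    discrete morphological character matrices with branch-and-bound and
    heuristic search, nonparametric bootstrap, and ensemble indices
    (consistency, homoplasy, retention, rescaled consistency); UPGMA
    distance trees from shape scores; craniodental ratio profiling
    against comparative ranges; jackknifed discriminant classification;
    a relative bite-force estimator; and allometric body-mass prediction
    from condylobasal skull length. Includes generators for synthetic
    landmark, character and measurement data so every stage of the
    pipeline is testable without museum specimens.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    MASS,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
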