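Package: tracheidGWAS
Title: Functional-Mapping Multi-Locus LASSO GWAS for Ring-Resolved Wood Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-stage association-mapping pipeline for ring-resolved
    (cambial-age indexed) wood tracheid traits measured on half-sib progeny
    trials, as used in conifer quantitative genetics. Stage 1 refines raw
    per-ring phenotypes with a joint-site univariate mixed model (EM-REML
    variance components, family BLUP breeding values). Stage 2 reduces each
    refined trajectory to latent traits: truncated-linear spline coefficients
    with two knots for dimension and coarseness traits, or core/outer means
    and a 20-degree transition age for microfibril angle. Stage 3 performs
    multi-locus LASSO association on the latent traits with principal-
    component population-structure covariates, declaring significance by
    stability selection with the Buhlmann expected-false-selection bound.
    Stage 4 characterises significant markers: adaptive-LASSO variance
    explained, genotype-class means, additive and dominance effects (2a, d,
    d/a) and Kruskal-Wallis class tests. A synthetic-data generator emulating
    the two-site, randomized-block, half-sib, ring-series design makes every
    stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    jsonlite,
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
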