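Package: opercle
Title: Outline Morphometrics and Phylogenetic Comparative Analysis of
    Opercle Shape Evolution
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying the evolution of opercle (gill cover)
    outline shape in fish species flocks such as the Lake Tanganyika
    cichlid radiation.  Reads TPS outline files, resamples closed curves
    to equidistant semilandmarks, performs generalized Procrustes
    superimposition and shape/form-space principal component ordination
    with broken-stick assessment, canonical variates analysis and
    permutation Procrustes ANOVA across feeding groups, phylogenetic
    generalized least squares against ecological covariates,
    maximum-likelihood fitting and AICc comparison of six trait-evolution
    models (Brownian motion, Ornstein-Uhlenbeck, white noise, Early
    Burst, Pagel's delta and lambda), Blomberg's K, pairwise
    distance-contrast convergence tests against Brownian simulations, and
    disparity-through-time curves with the morphological disparity index.
    A synthetic-data generator with known ground truth exercises every
    stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phytools,
    picante,
    nlme,
    MASS,
    vegan
Config/testthat/edition: 3
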