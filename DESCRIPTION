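Package: ptscam
Title: Cam-Mechanism Analysis of the Primate Talus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the posterior trochlear shelf (PTS) of the primate
    talus as a cam mechanism and traces its evolution across Euarchonta.
    Provides geometric measurement of the PTS index from triangle meshes
    (best-fit cylinder to the lateral tibial facet, curvature-based saddle
    landmarking of the flexor fibularis groove), a two-dimensional
    cam-follower model of tendon path length across ankle flexion, Brownian
    motion models with Pagel tree transforms fitted by maximum likelihood
    and MCMC with stepping-stone marginal likelihoods for Bayes-factor
    comparison, Bayesian ancestral state reconstruction, multi-regime
    Ornstein-Uhlenbeck fitting with stepwise regime-shift search and
    convergence collapse, clade-level statistics (one-sample t, pairwise
    ANOVA, OLS and PGLS regression), and a synthetic-data generator
    (talus-like meshes with known geometry; trees and traits simulated
    under BM and OU) so the whole pipeline is testable end to end.
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
    nlme,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    igraph,
    minpack.lm,
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
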