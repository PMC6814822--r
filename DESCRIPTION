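Package: ssdevol
Title: Macroevolution of Sexual Size Dimorphism on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative-methods pipeline for studying the evolution of
    sexual size dimorphism (SSD) on time-calibrated phylogenies. Computes
    the size dimorphism index (SDI) from sex-specific body masses, encodes
    social-system and dietary selective regimes, fits phylogenetic reduced
    major axis (RMA) regressions with simultaneous estimation of Pagel's
    lambda to test Rensch's rule, draws stochastic character maps of
    discrete regimes under Mk models, fits single- and multi-optimum
    Ornstein-Uhlenbeck models across map replicates with AICc model
    averaging and parametric-bootstrap confidence intervals, and locates
    SSD optimum shifts without a-priori regimes by reversible-jump MCMC
    with convergence diagnostics. Includes a synthetic-data generator so
    the full pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    expm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    coda,
    withr
Config/testthat/edition: 3
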