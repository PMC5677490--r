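Package: ouregimes
Title: Selective-Regime Models of Size-Corrected Limb Trait Diversification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the diversification of linear skeletal
    measurements on a dated phylogeny. Implements geometric-mean size
    correction with log-log least-squares residuals, covariance-matrix
    principal components with broken-stick significance, maximum-likelihood
    fitting of Brownian motion, multi-rate Brownian motion,
    Ornstein-Uhlenbeck (single- and multi-optimum), early-burst and
    white-noise models over regime-painted trees, stochastic character
    mapping of discrete locomotor habits with model averaging across
    mappings, reversible-jump MCMC detection of unconstrained shifts in
    phenotypic optima, AICc model comparison with phylogenetic half-life,
    and parametric-bootstrap (phylogenetic Monte Carlo) model-adequacy
    testing. Includes a synthetic-data generator that produces specimen-level
    trait tables, habit maps and dated trees with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
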