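Package: ouregimes
Title: Multi-Regime Ornstein-Uhlenbeck Models of Genome Size Evolution on
    Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Brownian-motion and multi-regime Ornstein-Uhlenbeck models
    of continuous trait evolution on ultrametric phylogenies, with regimes
    painted onto branches from species life-history states.  Provides exact
    multivariate-Gaussian likelihoods for regime-painted BM/OU processes,
    maximum-likelihood estimation with generalized-least-squares profiling of
    the regime equilibria, AICc model tables over a family of life-history
    hypotheses, parametric-bootstrap confidence intervals, a phylogenetic
    Monte Carlo model-comparison procedure (likelihood-difference statistic,
    approximate p-value and power), regime-wise stationary distributions, and
    a synthetic-data generator emulating a clade-structured salamander genome
    size study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    yaml
Suggests:
    phytools,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
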