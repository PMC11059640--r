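Package: cnphylo
Title: Bayesian Phylogenetic Inference from Single-Cell Copy-Number Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian inference of rooted, ultrametric single-cell phylogenies
    with branch lengths from binned copy-number profiles under a continuous-time
    linear birth-death model of copy-number evolution. Provides the birth-death
    transition kernel with a Gaussian observation-error model, a modified
    Felsenstein pruning likelihood with a diploid root stem, Metropolis-Hastings
    MCMC over ultrametric trees with a random local clock (optionally
    Metropolis-coupled), joint maximum-likelihood reconstruction of ancestral and
    error-corrected leaf copy-number profiles, a copy-number-aberration simulator
    that generates ground-truth data along a supplied tree, and posterior
    summaries (maximum clade credibility tree, median node heights, HPD
    intervals) together with topology and branch-length accuracy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    jsonlite
Config/testthat/edition: 3
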