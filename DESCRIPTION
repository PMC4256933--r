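Package: epibnn
Title: Bayesian Neural Networks for Detecting Epistasis in Case-Control
    Association Studies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a one-hidden-layer Bayesian neural network to case-control
    genotype data with automatic relevance determination (ARD) priors on the
    per-SNP weight groups, sampled by Hamiltonian Monte Carlo interleaved with
    conjugate Gibbs updates of the group variances. Posterior relevance
    probabilities give a significance test for causal and epistatically
    interacting SNPs without permutation testing. Includes simulators for
    two-locus relative-risk models and purely epistatic penetrance tables with
    controlled heritability, a chi-square marginal-effects baseline with
    Bonferroni correction, interaction-information entropy webs, and a
    power/false-positive-rate study harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp (>= 1.0.0),
    stats,
    utils,
    graphics,
    jsonlite,
    igraph
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
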