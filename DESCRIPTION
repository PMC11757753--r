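Package: turingnet
Title: Random-Matrix Analysis of Turing Instability Robustness in
    Reaction-Diffusion Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how often diffusion-driven (Turing)
    instabilities arise by chance in reaction-diffusion networks. Samples
    random Jacobian ensembles built on May's circular law (Gaussian
    interactions, fixed degradation, optional sparsity, antisymmetric and
    full-Gaussian variants), computes dispersion relations of J(k) = J0 -
    k^2 D with two diffusing species, classifies Turing I, Turing II and
    Turing-Hopf instabilities, and runs Monte-Carlo surveys over network
    size, interaction variance, sparsity and diffusion constants to locate
    the network size with the most robust Turing I patterning. Also
    includes a Hill-function gene-circuit generator (Latin-hypercube
    parameter screens, Newton-Raphson steady states, analytic Jacobians)
    and beta-distribution fitting of Jacobian-element samples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    lhs,
    yaml,
    jsonlite,
    e1071,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr,
    optparse
Config/testthat/edition: 3
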