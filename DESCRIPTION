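Package: coalABC
Title: Coalescent Simulation and Approximate Bayesian Computation for
    Multi-Population Phylogeography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for likelihood-free inference of multi-population
    divergence histories from multi-locus sequence data. Provides a
    coalescent simulator for population-tree scenarios with uniform
    priors, rejection-sampling approximate Bayesian computation with
    polychotomous logistic-regression scenario choice and local-linear
    parameter estimation, descriptive population-genetic statistics
    (haplotype and nucleotide diversity, Tajima's D, Fu's Fs,
    Ramos-Onsins and Rozas' R2, pairwise AMOVA Phi_ST), four-gamete
    recombination filtering with a pairwise homoplasy index test, and
    unrooted minimum-spanning haplotype networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    glmnet,
    igraph,
    Biostrings,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
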