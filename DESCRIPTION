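Package: coalsize
Title: Population Size History Inference with Coalescent Hidden Markov Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers piecewise-constant population size histories from unphased
    genomic polymorphism data with a coalescent hidden Markov model whose
    one-dimensional hidden state is either the time to the most recent common
    ancestor (TMRCA) or the total branch length of the local genealogy.
    Transition and emission probabilities are obtained from augmented
    ancestral processes with at most one recombination or mutation event,
    solved exactly by matrix exponentials (TMRCA) or by a characteristic
    transport scheme for the accumulated branch-length distributions.
    Parameters are estimated by an EM algorithm with a Nelder-Mead M-step in
    log coalescent-rate space and a composite likelihood over haplotype
    subsets, including a two-layer hypergeometric emission model for
    pseudo-haploid data. Includes a sequentially Markovian coalescent
    sequence simulator, VCF input, and accuracy metrics for simulation
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    Rcpp,
    tibble,
    dplyr,
    rlang,
    withr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
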