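Package: contibd
Title: Continuous Identity-by-Descent Models for Pedigree Relationship Testing
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact continuous-genome models of identity by descent (IBD)
    between two pedigree members under Haldane's recombination model.
    Provides construction of two-person pedigree relationships (linear,
    avuncular, cousin and half-relationships, or arbitrary PED-like
    pedigrees), simulation of continuously observed IBD segments along a
    genetic map, exact identity coefficients and moments of total IBD and
    segment count, probabilities of sharing no DNA via a uniformized
    forward algorithm, exact likelihoods of observed IBD segment sets, and
    Monte-Carlo likelihood-ratio power studies quantifying how well
    pedigree relationships can be distinguished from perfectly observed
    IBD.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
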