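Package: epiclock
Title: Epimutation Rate Inference from Pedigree-Based DNA Methylation Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the rate and spectrum of spontaneous epimutations
    (stochastic gains and losses of cytosine methylation) from
    pedigree-structured DNA methylation data.  Supports sexually (selfing)
    and clonally propagated mutation-accumulation lines as well as
    intra-organismal somatic phylogenies of long-lived perennials (tree
    branches dated by coring).  Methylation-state inheritance is modelled
    with diploid epigenotype Markov chains; gain rate, loss rate, selection
    and founder heterozygosity parameters are estimated by constrained
    nonlinear least squares on pairwise methylome divergence.  Includes
    residual-bootstrap confidence intervals, nested F-tests for selection
    versus neutrality, least-squares profiling of an unknown founder age
    (tree age dating), and a forward simulator of epigenotypes through
    arbitrary pedigrees that doubles as a Monte-Carlo oracle for the model.
License: GPL-3
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    methods,
    Rcpp,
    GenomicRanges,
    IRanges,
    rtracklayer,
    pracma
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
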