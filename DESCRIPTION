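Package: genefamevo
Title: Gene Family Evolution Analysis for Plant Nuclear Gene Families
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end toolkit for studying the evolution of plant
    nuclear gene families such as glutamine synthetase (GS) and
    phosphoenolpyruvate carboxylase (PEPC). Builds gene families from
    all-vs-all homology hits with an in-package Markov clustering (MCL)
    implementation and silhouette-based inflation selection;
    quality-controls codon alignments (gap-pattern outlier rejection,
    occupancy trimming, back-translation, rare-codon masking); infers
    neighbor-joining gene trees with bootstrap support; reconciles gene
    trees against a species tree under a duplication/loss parsimony model
    and classifies duplication timing; scans for selection with NG86
    Ka/Ks estimates and the branch-site likelihood ratio test of episodic
    positive selection (GY94 codon model, naive empirical Bayes site
    identification); quantifies droplet digital PCR assays by Poisson
    statistics; characterizes genome regions (GC content, repeat
    fraction, gene structures) and detects microsynteny blocks by anchor
    chaining. A simulation module generates gene families by birth-death
    duplication/loss with whole-genome-duplication events, codon
    alignments under site- and branch-specific dN/dS, and droplet assays,
    so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    igraph,
    cluster,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    rtracklayer,
    BiocGenerics,
    GenomeInfoDb
Config/testthat/edition: 3
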