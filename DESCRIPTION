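Package: cghindels
Title: Copy-Number Indel Calling and Strain Relatedness from Array CGH
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting deletions and amplifications
    in two-color array comparative genomic hybridization (aCGH) data and for
    inferring strain relationships from deletion markers. Provides robust
    LOWESS intensity normalization, a bottom-up t-test merging segmentation
    algorithm with breakpoint and flanking-probe determination, cross-strain
    matching of indel alleles into loci, gene annotation of affected regions,
    chromosome and arm/center enrichment statistics, Camin-Sokal and Wagner
    parsimony tree inference with bootstrap consensus support, and the
    standardized index of association for multilocus linkage disequilibrium.
    A synthetic-data module simulates exon-centric probe maps, strain
    genealogies with shared indels, and noisy ratio profiles with a known
    truth set so that every stage of the pipeline can be validated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    ape,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
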