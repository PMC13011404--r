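Package: pangloss
Title: Pangenome Openness, Gene Gain/Loss and Co-Occurrence Analysis for
    Bacterial Genome Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for dissecting the evolution of a bacterial pangenome:
    permutation-averaged gene accumulation curves with Heaps'-law openness
    fitting; core/soft-core/shell/cloud partitioning of gene presence/absence
    matrices; genome clustering from average nucleotide identity and Jaccard
    gene-content distances with elbow-method cluster selection, principal
    coordinates analysis and a permutation test for per-gene influence on
    the ordination; a four-factor codon-usage screen (RSCU deviation,
    effective number of codons, codon adaptation index, GC content) for
    high-confidence horizontally transferred genes with mobile-element
    context annotation; asymmetric-cost Wagner parsimony for per-family
    gene gain and loss on a phylogeny with permutation significance; and
    stratified Spearman co-occurrence networks with Benjamini-Hochberg
    false discovery control. Includes simulators with known ground truth
    for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    pracma,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
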