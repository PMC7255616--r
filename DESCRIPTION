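Package: locuskit
Title: Comparative Characterization of Vertebrate Gene Loci from Read Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative characterization of a vertebrate
    gene locus: simulation of genomes, gene models, isoform mixtures, retrocopies
    and neighbor-gene loci with known ground truth; assembly and arithmetic
    validation of exon/intron/UTR gene models; design of tiled and
    paralog-discriminating genomic probes; mapping of transcript 5' and 3' ends
    (including poly(A) signal and cleavage-site detection) from RNA-seq-like read
    evidence; pairwise global and best-local-block alignment with percent-identity
    tables and a progressive multiple alignment; detection and classification of
    expressed retrocopies; and anchored microsynteny comparison of gene loci.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
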