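Package: chromExpr
Title: Integrative Chromatin-State and Expression Analysis of Endothelial
    Transcription Factor Loss
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to integrate ChIP-seq and transcriptome data for studies of
    endothelial-to-mesenchymal transition driven by combined loss of the ETS
    transcription factors ERG and FLI1. Provides readers for BED/narrowPeak,
    bedGraph and tab-separated expression matrices; a seeded synthetic-data
    generator with planted chromatin states, peaks and an 8-group knockdown
    expression design; microarray-style probe filtering, probe collapse,
    Z-scoring, hierarchical clustering and regulation-pattern calling;
    peak interval analytics (overlap, top-N selection, nearest-TSS assignment,
    genomic-region classification, replicate correlation); a multivariate
    Bernoulli-emission hidden Markov model over binarized 200-bp bins with
    Baum-Welch training, Viterbi decoding and sparse-state merging;
    class-by-cluster Fisher enrichment, differential H3K27Ac calling and a
    five-criterion direct-target screen; and exact k-mer motif enrichment
    against shuffled or random backgrounds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
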