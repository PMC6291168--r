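## Constructors, accessors and show() methods for the core containers.

#' Construct a GenomeAnnotation
#'
#' @param genes `GRanges` with a `gene_id` metadata column, or a data.frame
#'   with columns `gene_id`, `chrom`, `start`, `end`, `strand` (1-based,
#'   closed coordinates).
#' @param chromSizes named integer vector of chromosome lengths (bp).
#' @return A [GenomeAnnotation-class] object.
#' @examples
#' ann <- GenomeAnnotation(
#'   data.frame(gene_id = "g1", chrom = "chr1", start = 101, end = 400,
#'              strand = "+"),
#'   chromSizes = c(chr1 = 1000))
#' tssSites(ann)
#' @export
GenomeAnnotation <- function(genes, chromSizes) {
    if (is.data.frame(genes)) {
        genes <- GRanges(seqnames = genes$chrom,
                         ranges = IRanges(genes$start, genes$end),
                         strand = genes$strand,
                         gene_id = genes$gene_id)
    }
    seqlevels(genes) <- names(chromSizes)
    seqlengths(genes) <- as.integer(chromSizes)
    genes <- sort(genes, ignore.strand = TRUE)
    new("GenomeAnnotation", genes = genes)
}

#' @rdname GenomeAnnotation
#' @param x a `GenomeAnnotation`.
#' @export
setMethod("genes", "GenomeAnnotation", function(x) x@genes)

#' @rdname GenomeAnnotation
#' @export
setMethod("chromSizes", "GenomeAnnotation",
          function(x) seqlengths(x@genes))

#' @rdname GenomeAnnotation
#' @export
setMethod("tssSites", "GenomeAnnotation", function(x) {
    gr <- x@genes
    pos <- ifelse(as.character(strand(gr)) == "+", start(gr), end(gr))
    GRanges(seqnames(gr), IRanges(pos, width = 1L), strand = strand(gr),
            gene_id = mcols(gr)$gene_id,
            seqlengths = seqlengths(gr))
})

#' @rdname GenomeAnnotation
#' @export
setMethod("tesSites", "GenomeAnnotation", function(x) {
    gr <- x@genes
    pos <- ifelse(as.character(strand(gr)) == "+", end(gr), start(gr))
    GRanges(seqnames(gr), IRanges(pos, width = 1L), strand = strand(gr),
            gene_id = mcols(gr)$gene_id,
            seqlengths = seqlengths(gr))
})

setMethod("show", "GenomeAnnotation", function(object) {
    cat("GenomeAnnotation:", length(object@genes), "genes on",
        length(seqlengths(object@genes)), "chromosomes\n")
})

#' Construct a PeakSet
#'
#' @param target ChIP target name.
#' @param condition condition label.
#' @param peaks `GRanges`; a numeric `score` column is required (defaulted to
#'   0 when absent) and `summit_offset` is added as `NA` when absent.
#' @return A [PeakSet-class], sorted by (chrom, start).
#' @export
PeakSet <- function(target, condition = "siControl", peaks = GRanges()) {
    if (is.null(mcols(peaks)$score))
        mcols(peaks)$score <- numeric(length(peaks))
    if (is.null(mcols(peaks)$summit_offset))
        mcols(peaks)$summit_offset <- rep(NA_integer_, length(peaks))
    peaks <- peaks[order(as.integer(seqnames(peaks)), start(peaks))]
    new("PeakSet", target = target, condition = condition, peaks = peaks)
}

#' @rdname PeakSet
#' @param x a `PeakSet`.
#' @export
setMethod("peaks", "PeakSet", function(x) x@peaks)

#' @rdname PeakSet
#' @export
setMethod("peakTarget", "PeakSet", function(x) x@target)

#' @rdname PeakSet
#' @export
setMethod("peakCondition", "PeakSet", function(x) x@condition)

#' @rdname PeakSet
#' @export
setMethod("length", "PeakSet", function(x) length(x@peaks))

setMethod("show", "PeakSet", function(object) {
    cat(sprintf("PeakSet: %d %s peaks (%s)\n", length(object@peaks),
                object@target, object@condition))
})

#' Construct a BinnedTrackSet
#'
#' @param binSize bin width (bp).
#' @param counts named list (by chromosome) of bin x mark matrices; column
#'   names of the first matrix define the mark order when `marks` is missing.
#' @param marks mark names.
#' @return A [BinnedTrackSet-class].
#' @export
BinnedTrackSet <- function(binSize, counts, marks = colnames(counts[[1]])) {
    if (is.null(marks))
        marks <- paste0("mark", seq_len(ncol(counts[[1]])))
    counts <- lapply(counts, function(m) {
        m <- as.matrix(m)
        colnames(m) <- marks
        m
    })
    new("BinnedTrackSet", binSize = as.integer(binSize),
        marks = as.character(marks), counts = counts)
}

#' @rdname BinnedTrackSet
#' @param x a `BinnedTrackSet`.
#' @export
setMethod("binSize", "BinnedTrackSet", function(x) x@binSize)

#' @rdname BinnedTrackSet
#' @export
setMethod("marks", "BinnedTrackSet", function(x) x@marks)

#' @rdname BinnedTrackSet
#' @export
setMethod("trackCounts", "BinnedTrackSet", function(x) x@counts)

#' @rdname BinnedTrackSet
#' @export
setMethod("nBins", "BinnedTrackSet",
          function(x) vapply(x@counts, nrow, integer(1)))

setMethod("show", "BinnedTrackSet", function(object) {
    cat(sprintf("%s: %d-bp bins, %d chromosome(s), marks: %s\n",
                class(object), object@binSize, length(object@counts),
                paste(object@marks, collapse = ", ")))
})

#' Construct a StateModel
#'
#' @param startProb initial state distribution.
#' @param transMat row-stochastic transition matrix.
#' @param emissionProb K x M Bernoulli emission matrix.
#' @param marks mark names (defaults to emission column names).
#' @param logLik training log-likelihood.
#' @return A [StateModel-class].
#' @export
StateModel <- function(startProb, transMat, emissionProb,
                       marks = colnames(emissionProb), logLik = NA_real_) {
    if (is.null(marks))
        marks <- paste0("mark", seq_len(ncol(emissionProb)))
    colnames(emissionProb) <- marks
    new("StateModel", startProb = startProb, transMat = transMat,
        emissionProb = emissionProb, marks = as.character(marks),
        logLik = logLik)
}

#' @rdname StateModel
#' @param x a `StateModel`.
#' @export
setMethod("nStates", "StateModel", function(x) length(x@startProb))

#' @rdname StateModel
#' @export
setMethod("startProb", "StateModel", function(x) x@startProb)

#' @rdname StateModel
#' @export
setMethod("transMat", "StateModel", function(x) x@transMat)

#' @rdname StateModel
#' @export
setMethod("emissionProb", "StateModel", function(x) x@emissionProb)

#' @rdname StateModel
#' @export
setMethod("marks", "StateModel", function(x) x@marks)

setMethod("show", "StateModel", function(object) {
    cat(sprintf("StateModel: %d states x %d marks, logLik %s\n",
                nStates(object), length(object@marks),
                format(object@logLik)))
})

#' @rdname StatePath-class
#' @param x a `StatePath`.
#' @export
setMethod("statePath", "StatePath", function(x) x@path)

#' @rdname StatePath-class
#' @export
setMethod("nStates", "StatePath", function(x) x@nStates)

#' @rdname StatePath-class
#' @export
setMethod("binSize", "StatePath", function(x) x@binSize)

setMethod("show", "StatePath", function(object) {
    cat(sprintf("StatePath: %d states over %d bins (%d chromosome(s))\n",
                object@nStates, sum(lengths(object@path)),
                length(object@path)))
})

#' Construct a KnockdownExpression object
#'
#' @param values probe x sample matrix of non-negative linear-scale signal.
#' @param probeToGene named character vector, probe id -> gene id.
#' @param sampleMeta data.frame with columns `treatment`, `day`, `replicate`,
#'   one row per sample (rownames or a `sample` column matching the matrix
#'   columns).
#' @return A [KnockdownExpression-class].
#' @export
KnockdownExpression <- function(values, probeToGene, sampleMeta) {
    if (!is.null(sampleMeta$sample))
        rownames(sampleMeta) <- sampleMeta$sample
    sampleMeta <- sampleMeta[colnames(values), , drop = FALSE]
    cd <- DataFrame(treatment = factor(as.character(sampleMeta$treatment),
                                       levels = .TREATMENTS),
                    day = factor(as.character(sampleMeta$day), levels = .DAYS),
                    replicate = as.integer(sampleMeta$replicate),
                    row.names = colnames(values))
    rd <- DataFrame(gene_id = unname(probeToGene[rownames(values)]),
                    row.names = rownames(values))
    new("KnockdownExpression",
        SummarizedExperiment(assays = list(signal = as.matrix(values)),
                             rowData = rd, colData = cd))
}

#' @rdname ClusterAssignment-class
#' @param x a `ClusterAssignment`.
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

setMethod("show", "ClusterAssignment", function(object) {
    tab <- table(object@labels)
    cat(sprintf("ClusterAssignment: %d genes in %d clusters (sizes: %s)\n",
                length(object@labels), length(tab),
                paste(as.integer(tab), collapse = ", ")))
})

#' @rdname PatternAssignment-class
#' @param x a `PatternAssignment`.
#' @export
setMethod("patternLabels", "PatternAssignment", function(x) x@labels)

setMethod("show", "PatternAssignment", function(object) {
    tab <- table(object@labels)
    cat("PatternAssignment:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
        "\n")
})
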