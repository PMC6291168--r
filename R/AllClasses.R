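## Central S4 containers.  All genomic intervals are held as GRanges
## (1-based, closed); BED-dialect 0-based half-open coordinates are converted
## at the reader/writer boundary.

#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

setClassUnion("ListOrNULL", c("list", "NULL"))

#' GenomeAnnotation: chromosome sizes plus stranded gene models
#'
#' Holds the gene annotation every stage consumes: a set of stranded gene
#' intervals together with chromosome lengths (stored as `seqlengths` on the
#' internal [GenomicRanges::GRanges]).  The transcription start site (TSS) of
#' a gene is its 5' end (`start` on `+`, `end` on `-`); the transcription end
#' site (TES) is the opposite end.
#'
#' @slot genes `GRanges` with a `gene_id` metadata column and defined
#'   `seqlengths`.
#'
#' @aliases GenomeAnnotation-class
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation", slots = c(genes = "GRanges"))

setValidity("GenomeAnnotation", function(object) {
    gr <- object@genes
    msg <- character()
    if (is.null(mcols(gr)$gene_id))
        msg <- c(msg, "genes must carry a 'gene_id' metadata column")
    else if (anyDuplicated(mcols(gr)$gene_id))
        msg <- c(msg, "gene_id values must be unique")
    sl <- seqlengths(gr)
    if (any(is.na(sl)))
        msg <- c(msg, "all chromosome lengths (seqlengths) must be defined")
    else if (length(gr)) {
        lens <- sl[as.character(seqnames(gr))]
        if (any(end(gr) > lens) || any(start(gr) < 1L))
            msg <- c(msg, "gene coordinates must lie within chromosome bounds")
    }
    if (length(gr) && any(!as.character(strand(gr)) %in% c("+", "-")))
        msg <- c(msg, "gene strand must be '+' or '-'")
    if (length(msg)) msg else TRUE
})

#' PeakSet: scored intervals for one ChIP target
#'
#' A set of scored peak intervals for a single ChIP-seq target (e.g. ERG,
#' FLI1 or H3K27Ac) in one condition.  Peaks are kept sorted by
#' (chromosome, start).  `summit_offset`, when present (narrowPeak input),
#' is the 0-based offset of the summit from the peak start, or `NA`.
#'
#' @slot target ChIP target name (mark or transcription factor).
#' @slot condition condition label (e.g. `"siControl"`).
#' @slot peaks `GRanges` with numeric `score` and integer `summit_offset`
#'   metadata columns.
#'
#' @aliases PeakSet-class
#' @exportClass PeakSet
setClass("PeakSet",
         slots = c(target = "character", condition = "character",
                   peaks = "GRanges"))

setValidity("PeakSet", function(object) {
    gr <- object@peaks
    msg <- character()
    if (length(object@target) != 1L || length(object@condition) != 1L)
        msg <- c(msg, "target and condition must be single strings")
    if (is.null(mcols(gr)$score))
        msg <- c(msg, "peaks must carry a numeric 'score' column")
    else if (any(!is.finite(mcols(gr)$score)))
        msg <- c(msg, "peak scores must be finite")
    if (is.null(mcols(gr)$summit_offset))
        msg <- c(msg, "peaks must carry a 'summit_offset' column (may be NA)")
    if (length(gr) > 1L && is.unsorted(order(as.integer(seqnames(gr)),
                                             start(gr))))
        msg <- c(msg, "peaks must be sorted by (chrom, start)")
    if (length(msg)) msg else TRUE
})

#' BinnedTrackSet: fixed-width binned signal for several marks
#'
#' Per-chromosome matrices of non-negative signal in non-overlapping,
#' genome-tiling bins of fixed width; one column per mark.  Chromosome `c`
#' of length `L` contributes `ceiling(L / binSize)` rows.
#'
#' @slot binSize bin width in bp.
#' @slot marks ordered mark names (matrix column order).
#' @slot counts named list (by chromosome) of `n_bins x length(marks)`
#'   numeric matrices.
#'
#' @aliases BinnedTrackSet-class
#' @exportClass BinnedTrackSet
setClass("BinnedTrackSet",
         slots = c(binSize = "integer", marks = "character",
                   counts = "list"))

setValidity("BinnedTrackSet", function(object) {
    msg <- character()
    if (length(object@binSize) != 1L || object@binSize < 1L)
        msg <- c(msg, "binSize must be a single positive integer")
    if (is.null(names(object@counts)) || anyDuplicated(names(object@counts)))
        msg <- c(msg, "counts must be a named list with unique chromosome names")
    for (m in object@counts) {
        if (!is.matrix(m) || ncol(m) != length(object@marks)) {
            msg <- c(msg, "each counts element must be a matrix with one column per mark")
            break
        }
        if (any(!is.finite(m)) || any(m < 0)) {
            msg <- c(msg, "counts must be finite and non-negative")
            break
        }
    }
    if (length(msg)) msg else TRUE
})

#' BinaryTrackSet: binarized binned signal
#'
#' Same shape as the [BinnedTrackSet] it was derived from, with entries in
#' \{0, 1\} (presence/absence calls per mark per bin).
#'
#' @aliases BinaryTrackSet-class
#' @exportClass BinaryTrackSet
setClass("BinaryTrackSet", contains = "BinnedTrackSet")

setValidity("BinaryTrackSet", function(object) {
    for (m in object@counts)
        if (any(m != 0 & m != 1))
            return("bits must be 0 or 1")
    TRUE
})

#' StateModel: parameters of a Bernoulli-emission HMM
#'
#' A hidden Markov model over binarized chromatin marks: initial state
#' distribution, row-stochastic transition matrix, and per-state independent
#' Bernoulli emission probabilities (one column per mark).
#'
#' @slot startProb initial distribution (length K, sums to 1).
#' @slot transMat K x K row-stochastic transition matrix.
#' @slot emissionProb K x M matrix of Bernoulli parameters in \[0, 1\].
#' @slot marks mark names (emission column order).
#' @slot logLik training log-likelihood (`NA` for hand-built models).
#'
#' @aliases StateModel-class
#' @exportClass StateModel
setClass("StateModel",
         slots = c(startProb = "numeric", transMat = "matrix",
                   emissionProb = "matrix", marks = "character",
                   logLik = "numeric"))

setValidity("StateModel", function(object) {
    K <- length(object@startProb)
    msg <- character()
    if (abs(sum(object@startProb) - 1) > 1e-10 || any(object@startProb < 0))
        msg <- c(msg, "startProb must be a probability distribution")
    if (!all(dim(object@transMat) == c(K, K)))
        msg <- c(msg, "transMat must be K x K")
    else if (any(abs(rowSums(object@transMat) - 1) > 1e-10) ||
             any(object@transMat < 0))
        msg <- c(msg, "transMat rows must each sum to 1 (tolerance 1e-10)")
    if (nrow(object@emissionProb) != K)
        msg <- c(msg, "emissionProb must have one row per state")
    if (ncol(object@emissionProb) != length(object@marks))
        msg <- c(msg, "emissionProb must have one column per mark")
    if (any(object@emissionProb < 0 | object@emissionProb > 1))
        msg <- c(msg, "emission probabilities must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' StatePath: per-bin chromatin-state assignment
#'
#' The decoded state label for every genomic bin, stored per chromosome, plus
#' (optionally) per-bin posterior state probabilities.
#'
#' @slot path named list (by chromosome) of integer vectors in `1..nStates`.
#' @slot nStates number of states labels may take.
#' @slot binSize bin width in bp (carried from the source track set).
#' @slot posterior optional named list of `n_bins x K` posterior matrices.
#'
#' @aliases StatePath-class
#' @exportClass StatePath
setClass("StatePath",
         slots = c(path = "list", nStates = "integer", binSize = "integer",
                   posterior = "ListOrNULL"))

setValidity("StatePath", function(object) {
    for (p in object@path) {
        if (!is.integer(p) || any(p < 1L) || any(p > object@nStates))
            return("path labels must be integers in 1..nStates")
    }
    if (is.null(names(object@path)))
        return("path must be a named list (by chromosome)")
    TRUE
})

#' KnockdownExpression: probe-level expression with knockdown design
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the normalized
#' linear-scale (MAS5-like) probe x sample signal matrix for the 8-group
#' design: 4 siRNA treatments (siControl, siERG, siFLI1, siERG+siFLI1)
#' crossed with 2 time points (day 3, day 7).  `rowData` maps probes to
#' genes; `colData` carries `treatment`, `day` and `replicate`.
#'
#' @aliases KnockdownExpression-class
#' @exportClass KnockdownExpression
setClass("KnockdownExpression", contains = "SummarizedExperiment")

.TREATMENTS <- c("siControl", "siERG", "siFLI1", "siERG+siFLI1")
.DAYS <- c("3", "7")

setValidity("KnockdownExpression", function(object) {
    msg <- character()
    cd <- colData(object)
    for (f in c("treatment", "day", "replicate"))
        if (!f %in% colnames(cd))
            msg <- c(msg, sprintf("colData must contain '%s'", f))
    if ("treatment" %in% colnames(cd) &&
        !all(as.character(cd$treatment) %in% .TREATMENTS))
        msg <- c(msg, paste0("treatment must be one of: ",
                             paste(.TREATMENTS, collapse = ", ")))
    if ("day" %in% colnames(cd) && !all(as.character(cd$day) %in% .DAYS))
        msg <- c(msg, "day must be 3 or 7")
    if (!"signal" %in% names(SummarizedExperiment::assays(object)))
        msg <- c(msg, "assay 'signal' is required")
    else {
        x <- assay(object, "signal")
        if (any(!is.finite(x)) || any(x < 0))
            msg <- c(msg, "signal values must be finite and non-negative")
        if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
            msg <- c(msg, "probe ids (rownames) must be unique")
    }
    if (!"gene_id" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must contain 'gene_id'")
    if (length(msg)) msg else TRUE
})

#' ClusterAssignment: gene clusters from the expression pipeline
#'
#' @slot labels named integer vector, gene -> cluster id; ids are contiguous
#'   from 1 and ordered by decreasing cluster size.
#' @slot zscores gene x group matrix of row Z-scores used for clustering.
#' @slot method linkage/distance descriptor.
#'
#' @aliases ClusterAssignment-class
#' @exportClass ClusterAssignment
setClass("ClusterAssignment",
         slots = c(labels = "integer", zscores = "matrix",
                   method = "character"))

setValidity("ClusterAssignment", function(object) {
    k <- max(object@labels)
    if (!identical(base::sort(unique(object@labels)), seq_len(k)))
        return("cluster ids must be contiguous from 1")
    if (is.null(names(object@labels)))
        return("labels must be named by gene")
    TRUE
})

#' PatternAssignment: day-3 regulation patterns
#'
#' Gene-wise regulation-pattern labels (`"I"`..`"VIII"` or `"other"`) from
#' the day-3 response to single and combined ERG/FLI1 knockdown, plus the
#' template table that defines the patterns.
#'
#' @slot labels named character vector, gene -> pattern.
#' @slot templates data.frame documenting the pattern templates.
#' @slot delta Z-score threshold used to discretize up/flat/down.
#'
#' @aliases PatternAssignment-class
#' @exportClass PatternAssignment
setClass("PatternAssignment",
         slots = c(labels = "character", templates = "data.frame",
                   delta = "numeric"))

#' SimulationConfig: parameters of the synthetic-data generator
#'
#' Defines one reproducible synthetic study: a small multi-chromosome genome,
#' a sticky-Markov hidden chromatin-state path emitting Poisson (optionally
#' negative-binomial) counts per mark per bin, ChIP peak sets consistent with
#' the planted states, and an 8-group expression matrix with planted cluster,
#' pattern and candidate-gene structure.  See [simulationConfig()] for
#' defaults and [simulateStudy()] for the orchestrated generator.
#'
#' @aliases SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         slots = c(seed = "integer", nChroms = "integer",
                   chromLength = "integer", binSize = "integer",
                   nStatesTrue = "integer", emissionRates = "matrix",
                   stickiness = "numeric", nGenes = "integer",
                   nProbes = "integer", nReplicates = "integer",
                   clusterSpec = "list", candidateSpec = "list",
                   noiseScale = "numeric", emissionFamily = "character",
                   nbSize = "numeric", peakRateMin = "numeric",
                   geneLengthRange = "integer", lowFlatFraction = "numeric",
                   baselineRange = "numeric", flatBaselineRange = "numeric",
                   lowFlatBaselineRange = "numeric", affinityRange = "numeric",
                   flatNoiseSd = "numeric"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    if (object@stickiness <= 0 || object@stickiness > 1)
        msg <- c(msg, "stickiness must lie in (0, 1]")
    er <- object@emissionRates
    if (nrow(er) != object@nStatesTrue)
        msg <- c(msg, "emissionRates must have nStatesTrue rows")
    if (any(er < 0))
        msg <- c(msg, "emission rates must be >= 0")
    if (anyDuplicated(er) > 0)
        msg <- c(msg, "emissionRates rows must be distinct")
    if (!object@emissionFamily %in% c("poisson", "nbinom"))
        msg <- c(msg, "emissionFamily must be 'poisson' or 'nbinom'")
    if (object@nProbes < object@nGenes)
        msg <- c(msg, "nProbes must be >= nGenes (every gene needs a probe)")
    ns <- vapply(object@clusterSpec, function(s) s$nGenes, numeric(1))
    if (sum(ns) > object@nGenes)
        msg <- c(msg, "cluster spec group sizes must sum to <= nGenes")
    for (s in object@clusterSpec)
        if (length(s$effects) != 8L)
            msg <- c(msg, sprintf(
                "cluster spec '%s' must give 8 group effects", s$label))
    if (length(msg)) msg else TRUE
})
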