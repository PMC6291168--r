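## Peak interval analytics: pairwise overlap summaries, top-N selection,
## nearest-TSS assignment, genomic-region classification and binned
## replicate correlation.

.peakMid <- function(gr) {
    GRanges(seqnames(gr), IRanges((start(gr) + end(gr)) %/% 2L, width = 1L))
}

#' Summarize the overlap between two peak sets
#'
#' A peak of one set "overlaps" when it shares at least `minOverlap` bp with
#' at least one peak of the other set.  `merged_shared` counts the merged
#' intervals of the intersection of the two (reduced) sets — a symmetric
#' Venn-style count of shared regions.
#'
#' @param a,b [PeakSet-class] objects.
#' @param minOverlap minimum shared bp (default 1; must be >= 1).
#' @return list with `n_a`, `n_b`, `n_a_overlapping_b`, `n_b_overlapping_a`,
#'   `merged_shared`.
#' @export
overlapPeaks <- function(a, b, minOverlap = 1L) {
    if (minOverlap < 1L) stop("minOverlap must be >= 1", call. = FALSE)
    ga <- peaks(a); gb <- peaks(b)
    hits <- findOverlaps(ga, gb, minoverlap = minOverlap,
                         ignore.strand = TRUE)
    shared <- reduce(GenomicRanges::intersect(reduce(ga, ignore.strand = TRUE),
                                              reduce(gb, ignore.strand = TRUE),
                                              ignore.strand = TRUE))
    shared <- shared[width(shared) >= minOverlap]
    list(n_a = length(ga), n_b = length(gb),
         n_a_overlapping_b = length(unique(queryHits(hits))),
         n_b_overlapping_a = length(unique(subjectHits(hits))),
         merged_shared = length(shared))
}

#' Select the top-scoring peaks
#'
#' Returns the `n` highest-score peaks; ties at the cut are broken by
#' (chrom, start), making the output deterministic and independent of input
#' order.  When fewer than `n` peaks exist, all are returned with a warning.
#'
#' @param x a [PeakSet-class].
#' @param n number of peaks to keep (>= 1).
#' @return A [PeakSet-class] (sorted by position, as always).
#' @export
selectTopPeaks <- function(x, n) {
    stopifnot(n >= 1)
    gr <- peaks(x)
    if (length(gr) <= n) {
        if (length(gr) < n)
            warning(sprintf("only %d peaks available (requested %d)",
                            length(gr), n), call. = FALSE)
        return(x)
    }
    ord <- order(-mcols(gr)$score, as.integer(seqnames(gr)), start(gr))
    PeakSet(peakTarget(x), peakCondition(x), gr[ord[seq_len(n)]])
}

#' Assign each peak to its nearest TSS
#'
#' Distance is measured from the peak midpoint to each TSS; the nearest gene
#' within `maxDist` is reported (beyond it, `NA`).  The signed distance is
#' negative when the peak lies 5' of the TSS in the gene's orientation.
#' Equidistant TSSs are broken toward the smaller gene coordinate.
#'
#' @param x a [PeakSet-class].
#' @param annotation a [GenomeAnnotation-class].
#' @param maxDist maximum assignment distance in bp (default 1e6).
#' @return data.frame with one row per peak: `chrom`, `start`, `end`,
#'   `gene_id` (NA when unassigned) and signed `distance`.
#' @export
assignNearestTSS <- function(x, annotation, maxDist = 1e6) {
    gr <- peaks(x)
    tss <- tssSites(annotation)
    mid <- (start(gr) + end(gr)) %/% 2L
    gene <- rep(NA_character_, length(gr))
    dist <- rep(NA_real_, length(gr))
    for (chrom in unique(as.character(seqnames(gr)))) {
        pi <- which(as.character(seqnames(gr)) == chrom)
        ti <- which(as.character(seqnames(tss)) == chrom)
        if (!length(ti)) next
        tpos <- start(tss)[ti]
        ord <- order(tpos, ti)          # position, then gene coordinate
        tpos <- tpos[ord]; tidx <- ti[ord]
        for (p in pi) {
            dd <- abs(mid[p] - tpos)
            best <- min(dd)
            if (best > maxDist) next
            cand <- which(dd == best)   # ties -> smaller coordinate first
            g <- tidx[cand[1]]
            gene[p] <- mcols(tss)$gene_id[g]
            dist[p] <- if (as.character(strand(tss))[g] == "+")
                mid[p] - start(tss)[g] else start(tss)[g] - mid[p]
        }
    }
    data.frame(chrom = as.character(seqnames(gr)), start = start(gr),
               end = end(gr), gene_id = gene, distance = dist,
               stringsAsFactors = FALSE)
}

#' Classify peaks into genomic regions
#'
#' Each peak is placed by its midpoint with precedence upstream > genic >
#' downstream > distal_intergenic.  "Upstream" is the `flank` bp 5' of any
#' TSS and "downstream" the `flank` bp 3' of any TES, both strand-aware;
#' "genic" is any gene body.
#'
#' @param x a [PeakSet-class].
#' @param annotation a [GenomeAnnotation-class].
#' @param flank flank width in bp (default 3000).
#' @return factor of labels (`upstream`, `genic`, `downstream`,
#'   `distal_intergenic`), one per peak.
#' @export
classifyRegions <- function(x, annotation, flank = 3000L) {
    gr <- genes(annotation)
    mids <- .peakMid(peaks(x))
    up <- suppressWarnings(trim(GenomicRanges::flank(gr, flank,
                                                     start = TRUE)))
    down <- suppressWarnings(trim(GenomicRanges::flank(gr, flank,
                                                       start = FALSE)))
    inUp <- countOverlaps(mids, up, ignore.strand = TRUE) > 0
    inGene <- countOverlaps(mids, gr, ignore.strand = TRUE) > 0
    inDown <- countOverlaps(mids, down, ignore.strand = TRUE) > 0
    lab <- rep("distal_intergenic", length(mids))
    lab[inDown] <- "downstream"
    lab[inGene] <- "genic"
    lab[inUp] <- "upstream"
    factor(lab, levels = c("upstream", "genic", "downstream",
                           "distal_intergenic"))
}

#' Correlation of two replicate track sets in coarse bins
#'
#' Both replicates are re-binned to `binSize` by summation (a partial final
#' bin is kept) and the Pearson correlation over all bins genome-wide is
#' returned per mark.
#'
#' @param rep1,rep2 [BinnedTrackSet-class] objects on the same genome with
#'   the same marks.
#' @param binSize target bin width in bp (default 10000; must be a multiple
#'   of the source bin size).
#' @return Named numeric vector of Pearson r, one per mark.
#' @export
replicateCorrelation <- function(rep1, rep2, binSize = 10000L) {
    stopifnot(identical(marks(rep1), marks(rep2)),
              identical(names(trackCounts(rep1)), names(trackCounts(rep2))))
    fac <- binSize / binSize(rep1)
    if (fac != round(fac) || fac < 1)
        stop("binSize must be a positive multiple of the source bin size",
             call. = FALSE)
    rebin <- function(ts) {
        do.call(rbind, lapply(trackCounts(ts), function(m) {
            grp <- (seq_len(nrow(m)) - 1L) %/% fac
            rowsum(m, grp)
        }))
    }
    m1 <- rebin(rep1); m2 <- rebin(rep2)
    vapply(seq_along(marks(rep1)), function(j) {
        if (sd(m1[, j]) == 0 || sd(m2[, j]) == 0)
            stop("constant track for mark ", marks(rep1)[j], call. = FALSE)
        cor(m1[, j], m2[, j])
    }, numeric(1)) |> setNames(marks(rep1))
}
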