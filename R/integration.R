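## Integrative statistics: exact hypergeometric (Fisher) enrichment of
## class-by-cluster gene lists, differential H3K27Ac region calling, window
## assignment of genes to chromatin classes, and the five-criterion
## ERG/FLI1 direct-target screen.

#' Upper-tail hypergeometric probability, exact in log space
#'
#' Computes `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (`K` successes in
#' a universe of `N`, `n` draws) by log-space summation of the exact pmf
#' terms (via `lchoose`) with a stable log-sum-exp; the shorter of the two
#' tails is summed and complemented when that is cheaper.  This is the
#' one-sided Fisher enrichment p-value for a 2x2 table with margins
#' (`K`, `n`) and overlap `k`.
#'
#' @param k overlap count(s); may be a vector.
#' @param K size of the first set.
#' @param n size of the second set.
#' @param N universe size.
#' @return `P(X >= k)`, in `(0, 1]`, one value per element of `k`.
#' @export
hypergeomTailP <- function(k, K, n, N) {
    stopifnot(length(K) == 1L, length(n) == 1L, length(N) == 1L,
              K <= N, n <= N)
    lo <- max(0L, K + n - N)
    hi <- min(K, n)
    if (any(k < lo | k > hi))
        stop("overlap k outside the hypergeometric support", call. = FALSE)
    supp <- lo:hi
    lpmf <- lchoose(K, supp) + lchoose(N - K, n - supp) - lchoose(N, n)
    if (length(k) == 1L) {
        ## tail-local log-sum-exp: stable for arbitrarily large margins
        lt <- lpmf[supp >= k]
        m <- max(lt)
        p <- exp(m) * sum(exp(lt - m))
    } else {
        ## vectorized cumulative tail from the top; terms are normalized by
        ## the global pmf maximum (for the universes this package handles,
        ## min(pmf)/max(pmf) >> double underflow, so this is exact)
        m <- max(lpmf)
        upper <- rev(cumsum(rev(exp(lpmf - m)))) * exp(m)
        p <- upper[match(k, supp)]
    }
    pmin(p, 1)
}

#' Fisher enrichment of chromatin classes against expression clusters
#'
#' For every (class, cluster) pair of gene lists, builds the 2x2 table over
#' the gene universe and computes the one-sided (enrichment) Fisher exact
#' p-value from the hypergeometric upper tail, plus an odds ratio (with a
#' Haldane 0.5 correction when any cell is zero).
#'
#' @param classGenes named list of gene-id vectors, one per chromatin class.
#' @param clusterGenes named list of gene-id vectors, one per expression
#'   cluster.
#' @param universe character vector of all genes under consideration; class
#'   and cluster lists are intersected with it.
#' @return data.frame with one row per pair: `class`, `cluster`, the four
#'   cells `n11`, `n10`, `n01`, `n00`, `odds_ratio` and `p`.
#' @export
fisherAssociation <- function(classGenes, clusterGenes, universe) {
    if (!length(universe)) stop("empty universe", call. = FALSE)
    universe <- unique(universe)
    N <- length(universe)
    rows <- list()
    for (cl in names(classGenes)) {
        a <- intersect(classGenes[[cl]], universe)
        for (cu in names(clusterGenes)) {
            b <- intersect(clusterGenes[[cu]], universe)
            n11 <- length(intersect(a, b))
            n10 <- length(a) - n11
            n01 <- length(b) - n11
            n00 <- N - n11 - n10 - n01
            p <- if (length(b) == 0L || length(a) == 0L) 1
                 else hypergeomTailP(n11, length(a), length(b), N)
            cells <- c(n11, n10, n01, n00)
            or <- if (any(cells == 0))
                ((n11 + 0.5) * (n00 + 0.5)) / ((n10 + 0.5) * (n01 + 0.5))
            else (n11 * n00) / (n10 * n01)
            rows[[length(rows) + 1L]] <-
                data.frame(class = cl, cluster = cu, n11 = n11, n10 = n10,
                           n01 = n01, n00 = n00, odds_ratio = or, p = p,
                           stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    attr(out, "universe_size") <- N
    out
}

#' Sum binned signal over regions
#'
#' Overlap-weighted sums of one mark's bin counts over a set of regions
#' (partial bins contribute proportionally to the overlap fraction).
#'
#' @param tracks a [BinnedTrackSet-class].
#' @param regions `GRanges`.
#' @param mark mark name.
#' @return Numeric vector of per-region totals.
#' @export
regionCounts <- function(tracks, regions, mark) {
    stopifnot(mark %in% marks(tracks))
    bs <- binSize(tracks)
    cnt <- trackCounts(tracks)
    out <- numeric(length(regions))
    for (i in seq_along(regions)) {
        chrom <- as.character(seqnames(regions))[i]
        if (!chrom %in% names(cnt)) next
        v <- cnt[[chrom]][, mark]
        s <- start(regions)[i]; e <- end(regions)[i]
        b0 <- (s - 1L) %/% bs
        b1 <- (e - 1L) %/% bs
        b1 <- min(b1, length(v) - 1L)
        acc <- 0
        for (b in b0:b1) {
            lo <- max(s, b * bs + 1L)
            hi <- min(e, (b + 1L) * bs)
            acc <- acc + v[b + 1L] * (hi - lo + 1L) / bs
        }
        out[i] <- acc
    }
    out
}

#' Call regions with differential H3K27Ac signal
#'
#' Compares knockdown against control signal region by region with an exact
#' two-sided binomial test under library-size (total-count) normalization:
#' with region counts `x_c`, `x_k` and library totals `T_c`, `T_k`, the
#' knockdown count is tested against
#' `Binomial(x_c + x_k, T_k / (T_c + T_k))`, the two-sided p-value taken as
#' twice the smaller tail (capped at 1).  P-values are Benjamini-Hochberg
#' adjusted across regions; a region is called `decreased`/`increased` when
#' `q < alpha` and the normalized |log2 fold change| passes `lfcMin`.
#'
#' @param regions `GRanges` of tested regions (typically the control-
#'   condition H3K27Ac peaks).
#' @param countControl,countKnockdown per-region signal totals (e.g. from
#'   [regionCounts()]).
#' @param totalControl,totalKnockdown library sizes; default to the sums of
#'   the region counts.
#' @param lfcMin minimum |log2FC| (default 1).
#' @param alpha BH FDR threshold (default 0.05).
#' @return The input `GRanges` with metadata columns `count_control`,
#'   `count_knockdown`, `log2fc`, `p`, `q`, `direction`.
#' @export
differentialK27ac <- function(regions, countControl, countKnockdown,
                              totalControl = sum(countControl),
                              totalKnockdown = sum(countKnockdown),
                              lfcMin = 1, alpha = 0.05) {
    if (totalControl <= 0 || totalKnockdown <= 0)
        stop("zero total counts", call. = FALSE)
    xc <- round(countControl); xk <- round(countKnockdown)
    n <- xc + xk
    p0 <- totalKnockdown / (totalControl + totalKnockdown)
    pvals <- vapply(seq_along(n), function(i) {
        if (n[i] == 0) return(1)
        lowerT <- pbinom(xk[i], n[i], p0)
        upperT <- pbinom(xk[i] - 1, n[i], p0, lower.tail = FALSE)
        min(1, 2 * min(lowerT, upperT))
    }, numeric(1))
    q <- p.adjust(pvals, method = "BH")
    log2fc <- log2((countKnockdown / totalKnockdown) /
                   (countControl / totalControl))
    direction <- rep("unchanged", length(n))
    direction[q < alpha & log2fc <= -lfcMin] <- "decreased"
    direction[q < alpha & log2fc >= lfcMin] <- "increased"
    out <- regions
    mcols(out)$count_control <- countControl
    mcols(out)$count_knockdown <- countKnockdown
    mcols(out)$log2fc <- log2fc
    mcols(out)$p <- pvals
    mcols(out)$q <- q
    mcols(out)$direction <- direction
    out
}

#' Genes associated with each chromatin class
#'
#' A gene belongs to class `c` when at least one bin decoded as `c` lies
#' within `window` bp of its TSS (the interval `[TSS - window, TSS +
#' window)`); a gene may belong to several classes.
#'
#' @param path a [StatePath-class].
#' @param annotation a [GenomeAnnotation-class].
#' @param window half-width of the TSS window in bp (default 25000).
#' @return Named list (class `"1"`..`"K"`) of gene-id vectors.
#' @export
genesForClass <- function(path, annotation, window = 25000L) {
    bs <- binSize(path)
    tss <- tssSites(annotation)
    out <- rep(list(character(0)), nStates(path))
    names(out) <- as.character(seq_len(nStates(path)))
    pchrom <- statePath(path)
    for (i in seq_along(tss)) {
        chrom <- as.character(seqnames(tss))[i]
        if (!chrom %in% names(pchrom)) next
        p <- pchrom[[chrom]]
        tpos <- start(tss)[i]
        ## bins overlapping [tss - window, tss + window) (1-based closed
        ## interval [tss - window, tss + window - 1])
        lo <- max(1L, (tpos - window - 1L) %/% bs + 1L)
        hi <- min(length(p), (tpos + window - 2L) %/% bs + 1L)
        if (lo > hi) next
        for (cls in unique(p[lo:hi]))
            out[[cls]] <- c(out[[cls]], mcols(tss)$gene_id[i])
    }
    lapply(out, unique)
}

#' Five-criterion ERG/FLI1 direct-target screen
#'
#' Flags, per gene: (a) `has_upstream_peak` — at least one ERG peak and one
#' FLI1 peak (or either, with `tfMode = "either"`) whose midpoint lies
#' within `upstreamWindow` bp of the TSS; (b) `peak_in_k27ac` — at least one
#' such TF peak overlapping (>= 1 bp) a control-condition H3K27Ac peak;
#' (c) `k27ac_reduced` — such an H3K27Ac peak intersects a region called
#' `decreased` by [differentialK27ac()]; (d) `expr_reduced_70` — the day-3
#' siERG+siFLI1 mean is reduced relative to the day-3 siControl mean by
#' strictly more than `reductionFrac`; (e) `combo_exceeds_singles` — day-3 combined-knockdown
#' mean strictly below both single-knockdown means.  A gene is a candidate
#' iff all five flags hold.  Genes absent from the expression matrix get
#' flags (d) and (e) `FALSE` with a warning.
#'
#' @param erg,fli1 TF [PeakSet-class] objects.
#' @param k27acControl control-condition H3K27Ac [PeakSet-class].
#' @param diff `GRanges` from [differentialK27ac()].
#' @param exprGeneMeans gene x group matrix (from [collapseProbes()], or any
#'   gene-level [groupMeans()]-style matrix).
#' @param annotation a [GenomeAnnotation-class].
#' @param upstreamWindow TSS window in bp (default 25000).
#' @param reductionFrac required expression reduction (default 0.70).
#' @param tfMode `"both"` (default) requires ERG and FLI1 peaks; `"either"`
#'   accepts one of the two.
#' @return data.frame with one row per annotated gene: the five logical
#'   flags and `is_candidate`.
#' @export
candidateScreen <- function(erg, fli1, k27acControl, diff, exprGeneMeans,
                            annotation, upstreamWindow = 25000L,
                            reductionFrac = 0.70,
                            tfMode = c("both", "either")) {
    tfMode <- match.arg(tfMode)
    tss <- tssSites(annotation)
    geneIds <- mcols(tss)$gene_id
    ergMid <- .peakMid(peaks(erg))
    fliMid <- .peakMid(peaks(fli1))
    k27 <- peaks(k27acControl)
    dec <- diff[mcols(diff)$direction == "decreased"]

    ## TF peaks whose midpoint is within the window of each TSS
    win <- GRanges(seqnames(tss),
                   IRanges(pmax(1L, start(tss) - upstreamWindow),
                           start(tss) + upstreamWindow))
    ergHits <- findOverlaps(win, ergMid, ignore.strand = TRUE)
    fliHits <- findOverlaps(win, fliMid, ignore.strand = TRUE)
    ## K27Ac peaks that overlap a decreased region
    k27Reduced <- countOverlaps(k27, dec, ignore.strand = TRUE) > 0

    ergByGene <- split(subjectHits(ergHits), queryHits(ergHits))
    fliByGene <- split(subjectHits(fliHits), queryHits(fliHits))

    hasUp <- logical(length(tss))
    inK27 <- logical(length(tss))
    reduced <- logical(length(tss))
    for (i in seq_along(tss)) {
        ei <- ergByGene[[as.character(i)]]
        fi <- fliByGene[[as.character(i)]]
        hasUp[i] <- if (tfMode == "both") length(ei) > 0 && length(fi) > 0
                    else length(ei) > 0 || length(fi) > 0
        if (!hasUp[i]) next
        tfPeaks <- c(peaks(erg)[ei], peaks(fli1)[fi])
        ov <- findOverlaps(tfPeaks, k27, ignore.strand = TRUE)
        inK27[i] <- length(ov) > 0
        if (inK27[i])
            reduced[i] <- any(k27Reduced[unique(subjectHits(ov))])
    }

    g3 <- function(treatment) paste(treatment, "3", sep = ".")
    known <- geneIds %in% rownames(exprGeneMeans)
    if (any(!known))
        warning(sum(!known), " gene(s) absent from the expression matrix; ",
                "expression criteria set to FALSE", call. = FALSE)
    expr70 <- combo <- logical(length(tss))
    if (any(known)) {
        em <- exprGeneMeans[geneIds[known], , drop = FALSE]
        ctrl <- em[, g3("siControl")]
        sE <- em[, g3("siERG")]
        sF <- em[, g3("siFLI1")]
        sEF <- em[, g3("siERG+siFLI1")]
        ## "reduced by more than reductionFrac" computed as a reduction
        ## fraction (avoids 1 - 0.70 floating-point slack at the boundary)
        expr70[known] <- ctrl > 0 & (ctrl - sEF) / ctrl > reductionFrac
        combo[known] <- sEF < sE & sEF < sF
    }

    data.frame(gene_id = geneIds,
               has_upstream_peak = hasUp,
               peak_in_k27ac = inK27,
               k27ac_reduced = reduced,
               expr_reduced_70 = expr70,
               combo_exceeds_singles = combo,
               is_candidate = hasUp & inK27 & reduced & expr70 & combo,
               stringsAsFactors = FALSE)
}
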