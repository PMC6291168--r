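## Expression pipeline: 8-group means, signal/CV probe filtering, probe
## collapse, row Z-scoring, agglomerative clustering (correlation distance,
## average linkage) and day-3 regulation-pattern calling.

.groupKey <- function(treatment, day) paste(treatment, day, sep = ".")

.GROUPS <- as.vector(outer(.TREATMENTS, .DAYS, .groupKey))

#' Per-group means of an expression matrix
#'
#' Arithmetic means on the linear signal scale over the replicates of each
#' of the 8 (treatment, day) groups.
#'
#' @param x a [KnockdownExpression-class].
#' @return probe x group matrix with columns `"<treatment>.<day>"` in the
#'   fixed design order (siControl, siERG, siFLI1, siERG+siFLI1 crossed with
#'   days 3 and 7).
#' @export
groupMeans <- function(x) {
    cd <- colData(x)
    key <- .groupKey(as.character(cd$treatment), as.character(cd$day))
    missing <- setdiff(.GROUPS, unique(key))
    if (length(missing)) {
        parts <- strsplit(missing[1], ".", fixed = TRUE)[[1]]
        stop(sprintf("no samples for (%s, day %s)", parts[1], parts[2]),
             call. = FALSE)
    }
    vals <- assay(x, "signal")
    out <- do.call(cbind, lapply(.GROUPS, function(g)
        rowMeans(vals[, key == g, drop = FALSE])))
    dimnames(out) <- list(rownames(vals), .GROUPS)
    out
}

#' Filter probes on signal level and variability
#'
#' A probe is retained when (1) its maximum group mean is at least
#' `minSignal` and (2) its coefficient of variation over the 8 group means
#' (sample sd with n-1 denominator, divided by the mean) is at least
#' `minCV`.  Both comparisons are inclusive.  All-zero probes have an
#' undefined CV and are excluded.
#'
#' @param gm probe x group matrix from [groupMeans()].
#' @param minSignal linear-scale signal threshold (default 300).
#' @param minCV coefficient-of-variation threshold (default 0.5).
#' @return Character vector of retained probe ids.
#' @export
filterProbes <- function(gm, minSignal = 300, minCV = 0.5) {
    stopifnot(minSignal > 0, minCV >= 0)
    mu <- rowMeans(gm)
    sdv <- apply(gm, 1L, sd)
    cv <- ifelse(mu > 0, sdv / mu, NA_real_)
    keep <- apply(gm, 1L, max) >= minSignal & !is.na(cv) & cv >= minCV
    rownames(gm)[keep]
}

#' Collapse probes to genes
#'
#' Among a gene's retained probes, exactly the probe with the largest sum of
#' its 8 group means is kept; exact ties are broken toward the
#' lexicographically smaller probe id (with a warning).
#'
#' @param probes retained probe ids (from [filterProbes()]).
#' @param gm probe x group matrix from [groupMeans()].
#' @param probeToGene named character vector, probe -> gene.
#' @return gene x group matrix (rownames are gene ids); attribute
#'   `"probe"` records the selected probe per gene.
#' @export
collapseProbes <- function(probes, gm, probeToGene) {
    if (any(!probes %in% names(probeToGene)))
        stop("probe without gene mapping: ",
             probes[!probes %in% names(probeToGene)][1], call. = FALSE)
    gm <- gm[probes, , drop = FALSE]
    genes <- probeToGene[probes]
    sums <- rowSums(gm)
    sel <- vapply(split(seq_along(probes), genes), function(idx) {
        s <- sums[idx]
        best <- idx[s == max(s)]
        if (length(best) > 1L) {
            best <- best[order(probes[best])]
            warning("probe-sum tie for gene ", genes[best[1]],
                    "; keeping ", probes[best[1]], call. = FALSE)
        }
        best[1]
    }, integer(1))
    out <- gm[sel, , drop = FALSE]
    rownames(out) <- names(sel)
    attr(out, "probe") <- setNames(probes[sel], names(sel))
    out
}

.rowZ <- function(m) {
    mu <- rowMeans(m)
    sdv <- apply(m, 1L, sd)
    if (any(sdv == 0))
        stop("zero-variance row reached clustering: ",
             rownames(m)[sdv == 0][1],
             " (should have been removed by the CV filter)", call. = FALSE)
    (m - mu) / sdv
}

#' Cluster genes on their Z-scored group profiles
#'
#' Rows are Z-scored across the 8 group means (mean 0, sd 1, n-1 sd), then
#' clustered agglomeratively with correlation distance (`1 - Pearson r`
#' between row profiles) and average linkage, cut at `kMajor` clusters.
#' Cluster ids are renumbered by decreasing size.  This is the package's
#' documented substitute for the HOPACH algorithm.
#'
#' @param geneMatrix gene x group matrix from [collapseProbes()].
#' @param kMajor number of clusters.
#' @return A [ClusterAssignment-class].
#' @export
clusterGenes <- function(geneMatrix, kMajor) {
    stopifnot(nrow(geneMatrix) >= kMajor)
    z <- .rowZ(geneMatrix)
    d <- as.dist(1 - cor(t(z)))
    hc <- hclust(d, method = "average")
    raw <- cutree(hc, k = kMajor)
    ## contiguous ids ordered by descending size (ties: first appearance)
    sizes <- table(raw)
    ord <- names(sizes)[order(-as.integer(sizes), as.integer(names(sizes)))]
    labels <- setNames(as.integer(match(as.character(raw), ord)),
                       names(raw))
    new("ClusterAssignment", labels = labels,
        zscores = z, method = "agglomerative/correlation/average")
}

#' Re-cut one cluster into sub-clusters
#'
#' Splits the genes of cluster `cluster` into `k2` sub-clusters with the
#' same distance/linkage, mirroring the sub-division of the synergistic
#' cluster into day-3- and day-7-upregulated sub-clusters.  Sub-cluster ids
#' are appended after the existing ids.
#'
#' @param assignment a [ClusterAssignment-class].
#' @param geneMatrix the matrix that produced it.
#' @param cluster cluster id to split.
#' @param k2 number of sub-clusters (default 2).
#' @return A new [ClusterAssignment-class] with `max(labels) + k2 - 1`
#'   clusters, renumbered by descending size.
#' @export
recutCluster <- function(assignment, geneMatrix, cluster, k2 = 2L) {
    lab <- clusterLabels(assignment)
    inC <- names(lab)[lab == cluster]
    stopifnot(length(inC) >= k2)
    sub <- clusterGenes(geneMatrix[inC, , drop = FALSE], k2)
    lab2 <- lab
    lab2[inC] <- max(lab) + clusterLabels(sub)[inC]
    ## renumber by descending size (also restores contiguity)
    sizes <- table(lab2)
    ord <- names(sizes)[order(-as.integer(sizes), as.integer(names(sizes)))]
    newLab <- setNames(as.integer(match(as.character(lab2), ord)),
                       names(lab2))
    new("ClusterAssignment", labels = newLab, zscores = assignment@zscores,
        method = assignment@method)
}

#' Regulation-pattern templates
#'
#' The eight day-3 regulation patterns, encoded from the knockdown responses
#' (siERG, siFLI1, siERG+siFLI1 each discretized to up/flat/down relative to
#' siControl at a Z-score threshold `delta`):
#' \describe{
#'   \item{I}{cooperative repression, ERG predominant: combo up, ERG up,
#'     FLI1 lesser.}
#'   \item{II}{cooperative repression, FLI1 predominant.}
#'   \item{III}{redundant repression: both single knockdowns up, nearly
#'     equal.}
#'   \item{IV}{ERG represses; FLI1 knockdown partially counteracts (combo up
#'     but clearly below siERG).}
#'   \item{V}{ERG represses; FLI1 knockdown completely counteracts (combo
#'     flat).}
#'   \item{VI}{opposing: ERG promotes (siERG down), FLI1 represses (siFLI1
#'     up).}
#'   \item{VII}{cooperative promotion, ERG predominant: combo down, ERG
#'     down.}
#'   \item{VIII}{cooperative promotion, FLI1 predominant.}
#' }
#'
#' @return data.frame describing the templates.
#' @export
patternTemplates <- function() {
    data.frame(
        pattern = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII"),
        siERG  = c("up", "flat/up", "up", "up", "up", "down", "down",
                   "flat/down"),
        siFLI1 = c("flat/up", "up", "up", "flat", "flat", "up", "flat/down",
                   "down"),
        combo  = c("up (>= siERG)", "up (>= siFLI1)", "up", "up (< siERG)",
                   "flat", "any", "down", "down"),
        role = c("cooperative repression, ERG predominant",
                 "cooperative repression, FLI1 predominant",
                 "redundant repression",
                 "ERG repression partially counteracted by siFLI1",
                 "ERG repression completely counteracted by siFLI1",
                 "opposing: ERG promotes, FLI1 represses",
                 "cooperative promotion, ERG predominant",
                 "cooperative promotion, FLI1 predominant"))
}

.classifyOne <- function(zE, zF, zC, delta) {
    d <- function(z) if (z >= delta) 1L else if (z <= -delta) -1L else 0L
    dE <- d(zE); dF <- d(zF); dC <- d(zC)
    if (dE == -1L && dF == 1L) return("VI")
    if (dE == 1L || dF == 1L) {           # repression side
        if (dC == 1L) {
            if (dE == 1L && dF == 1L) {
                if (abs(zE - zF) < delta) return("III")
                return(if (zE > zF) "I" else "II")
            }
            if (dE == 1L)
                return(if (zC <= zE - delta) "IV" else "I")
            return("II")
        }
        if (dC == 0L && dE == 1L && dF != 1L) return("V")
        return("other")
    }
    if (dE == -1L || dF == -1L) {         # promotion side
        if (dC == -1L) {
            if (dE == -1L && dF == -1L)
                return(if (zF <= zE - delta) "VIII" else "VII")
            return(if (dE == -1L) "VII" else "VIII")
        }
        return("other")
    }
    "other"
}

#' Classify day-3 regulation patterns
#'
#' Expression is re-normalized within the day-3 groups only: each gene's
#' 4-vector of day-3 group means is Z-scored, every treatment is discretized
#' to up/flat/down relative to siControl at threshold `delta` (in Z units),
#' and the signed (siERG, siFLI1, combo) triple is matched to the templates
#' of [patternTemplates()].  Unmatched genes are labeled `"other"`.
#'
#' @param geneMatrix gene x group matrix (8 columns as from
#'   [collapseProbes()]); the day-3 columns are used.
#' @param delta Z-score threshold for up/down calls (default 0.5; must be
#'   positive).
#' @return A [PatternAssignment-class].
#' @export
classifyPatterns <- function(geneMatrix, delta = 0.5) {
    if (delta <= 0) stop("delta must be > 0", call. = FALSE)
    d3 <- geneMatrix[, .groupKey(.TREATMENTS, "3"), drop = FALSE]
    mu <- rowMeans(d3)
    sdv <- apply(d3, 1L, sd)
    labels <- vapply(seq_len(nrow(d3)), function(i) {
        if (sdv[i] == 0) return("other")   # flat at day 3
        z <- (d3[i, ] - mu[i]) / sdv[i]
        zc <- z - z[1]                      # relative to siControl
        .classifyOne(zc[2], zc[3], zc[4], delta)
    }, character(1))
    new("PatternAssignment",
        labels = setNames(labels, rownames(d3)),
        templates = patternTemplates(), delta = delta)
}
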