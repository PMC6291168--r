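## De novo k-mer motif enrichment (exact enumeration, both strands,
## canonical collapse) against a shuffled or uniform-random background, and
## IUPAC-consensus motif frequency comparison between two region classes.

#' Dinucleotide-preserving sequence shuffle
#'
#' Shuffles each sequence while preserving its exact dinucleotide counts
#' (Altschul-Erickson Euler-path shuffle): the sequence is viewed as an
#' Eulerian walk on the symbol graph, a random last-edge arborescence to the
#' final symbol is drawn, remaining edges are permuted, and the walk is
#' reassembled.  Seeded and deterministic.
#'
#' @param seqs a [Biostrings::DNAStringSet] (or character vector).
#' @param seed integer seed.
#' @return A `DNAStringSet` of shuffled sequences.
#' @export
dinucShuffle <- function(seqs, seed = 1L) {
    set.seed(seed)
    seqs <- as.character(DNAStringSet(seqs))
    out <- vapply(seqs, function(s) {
        ch <- strsplit(s, "")[[1]]
        n <- length(ch)
        if (n < 3L) return(s)
        syms <- unique(ch)
        last <- ch[n]
        ## edges: from ch[i] to ch[i+1]
        from <- ch[-n]; to <- ch[-1L]
        edges <- split(to, factor(from, levels = syms))
        ## random arborescence toward `last`: for every other symbol pick a
        ## final edge lying on a path to `last` (rejection over random picks)
        repeat {
            lastEdge <- setNames(rep(NA_character_, length(syms)), syms)
            for (v in setdiff(syms, last)) {
                outs <- edges[[v]]
                lastEdge[v] <- outs[sample.int(length(outs), 1L)]
            }
            ## check: following last edges from each vertex reaches `last`
            okAll <- TRUE
            for (v in setdiff(syms, last)) {
                cur <- v; seen <- character(0)
                while (!is.na(cur) && cur != last && !(cur %in% seen)) {
                    seen <- c(seen, cur)
                    cur <- if (cur %in% names(lastEdge)) lastEdge[[cur]]
                           else NA_character_
                }
                if (is.na(cur) || cur != last) { okAll <- FALSE; break }
            }
            if (okAll) break
        }
        ## permute the remaining edges per vertex, append the fixed last edge
        lists <- lapply(syms, function(v) {
            outs <- edges[[v]]
            if (v != last) {
                drop <- match(lastEdge[[v]], outs)
                outs <- outs[-drop]
            }
            outs <- outs[sample.int(length(outs))]
            if (v != last) outs <- c(outs, lastEdge[[v]])
            outs
        })
        names(lists) <- syms
        ptr <- setNames(rep(1L, length(syms)), syms)
        res <- character(n)
        res[1] <- ch[1]
        cur <- ch[1]
        for (i in 2:n) {
            nxt <- lists[[cur]][ptr[[cur]]]
            ptr[[cur]] <- ptr[[cur]] + 1L
            res[i] <- nxt
            cur <- nxt
        }
        paste(res, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    DNAStringSet(out)
}

.uniformRandomSeqs <- function(lengths, seed) {
    set.seed(seed)
    DNAStringSet(vapply(lengths, function(L)
        paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
              collapse = ""), character(1)))
}

## canonical-kmer index: for every k-mer, the lexicographically smaller of
## itself and its reverse complement
.canonicalMap <- function(k) {
    all <- mkAllStrings(c("A", "C", "G", "T"), k)
    rc <- as.character(reverseComplement(DNAStringSet(all)))
    pmin(all, rc)
}

## both-strand canonical k-mer counts for a sequence set (overlapping
## windows; windows containing non-ACGT letters are skipped by
## oligonucleotideFrequency)
.kmerCounts <- function(seqs, k, canon = .canonicalMap(k)) {
    fwd <- oligonucleotideFrequency(seqs, width = k,
                                    simplify.as = "collapsed")
    rev <- oligonucleotideFrequency(reverseComplement(seqs), width = k,
                                    simplify.as = "collapsed")
    cnt <- fwd + rev
    rowsum(cnt, canon)[, 1]
}

#' Exact k-mer enrichment against a background
#'
#' Counts all k-mers (default 8-mers) in the foreground sequences on both
#' strands with overlaps allowed, collapsed to the canonical (lexicographic
#' minimum of k-mer and reverse complement) form, against either a
#' per-sequence dinucleotide shuffle of the foreground (default), uniform
#' random sequences of matched lengths, or explicit background sequences.
#' K-mers whose foreground/background frequency ratio reaches `foldMin` are
#' reported, ranked by one-sided Fisher enrichment p (window-count 2x2
#' table via [hypergeomTailP()]).
#'
#' @param fg foreground `DNAStringSet` (or character).
#' @param k k-mer width (default 8).
#' @param bgMode `"shuffle"` (dinucleotide shuffle) or `"uniform"`.
#' @param foldMin minimum fold enrichment reported (default 2).
#' @param seed seed for background generation.
#' @param bg explicit background sequences (overrides `bgMode`).
#' @return data.frame with `kmer`, `fg_count`, `bg_count`, `fold`, `p`,
#'   ordered by increasing p then decreasing fold.
#' @export
kmerEnrichment <- function(fg, k = 8L, bgMode = c("shuffle", "uniform"),
                           foldMin = 2, seed = 1L, bg = NULL) {
    bgMode <- match.arg(bgMode)
    fg <- DNAStringSet(fg)
    if (!length(fg)) stop("empty sequence set", call. = FALSE)
    if (min(BiocGenerics::width(fg)) < k)
        stop("k exceeds the shortest sequence length", call. = FALSE)
    if (is.null(bg)) {
        bg <- if (bgMode == "shuffle") dinucShuffle(fg, seed = seed)
              else .uniformRandomSeqs(BiocGenerics::width(fg), seed = seed)
    } else bg <- DNAStringSet(bg)
    canon <- .canonicalMap(k)
    fgc <- .kmerCounts(fg, k, canon)
    bgc <- .kmerCounts(bg, k, canon)
    fgTot <- sum(fgc); bgTot <- sum(bgc)
    fold <- (fgc / fgTot) / (bgc / bgTot)
    fold[fgc == 0] <- 0
    pass <- which(is.finite(fold) & fold >= foldMin | (fold == Inf & fgc > 0))
    p <- vapply(pass, function(i)
        hypergeomTailP(fgc[i], fgc[i] + bgc[i], fgTot, fgTot + bgTot),
        numeric(1))
    out <- data.frame(kmer = names(fgc)[pass], fg_count = fgc[pass],
                      bg_count = bgc[pass], fold = fold[pass], p = p,
                      stringsAsFactors = FALSE)
    out <- out[order(out$p, -out$fold, out$kmer), ]
    rownames(out) <- NULL
    out
}

#' Built-in motif consensus patterns
#'
#' IUPAC consensus motifs recurrent in ERG/FLI1 biology: the ETS core
#' (GGAW), the AP-1 element (TGASTCA) and the tandem GGAA repeat
#' (GGAAGGAA) enriched at cooperatively bound endothelial enhancers.
#'
#' @return data.frame with `name` and `consensus`.
#' @export
builtinMotifs <- function() {
    data.frame(name = c("ETS_core", "AP1", "GGAA_repeat"),
               consensus = c("GGAW", "TGASTCA", "GGAAGGAA"),
               stringsAsFactors = FALSE)
}

#' Compare motif frequency between two sequence classes
#'
#' The frequency of a motif (IUPAC consensus, matched exactly on either
#' strand) is the fraction of sequences with at least one match.  The
#' difference between the two classes is evaluated with a one-sided Fisher
#' exact test (enrichment in class A) on the sequences-with-match by class
#' 2x2 table.
#'
#' @param seqsA,seqsB `DNAStringSet` (or character) for the two classes.
#' @param motif IUPAC consensus string (e.g. `"GGAW"`), or a row name from
#'   [builtinMotifs()].
#' @return list with `freq_a`, `freq_b`, `n_a`, `n_b` and `p`.
#' @export
compareMotifFrequency <- function(seqsA, seqsB, motif) {
    bm <- builtinMotifs()
    if (motif %in% bm$name) motif <- bm$consensus[match(motif, bm$name)]
    seqsA <- DNAStringSet(seqsA); seqsB <- DNAStringSet(seqsB)
    if (!length(seqsA) || !length(seqsB))
        stop("empty sequence set", call. = FALSE)
    hasMatch <- function(seqs) {
        f <- vcountPattern(motif, seqs, fixed = FALSE) > 0
        r <- vcountPattern(motif, reverseComplement(seqs), fixed = FALSE) > 0
        f | r
    }
    a <- hasMatch(seqsA); b <- hasMatch(seqsB)
    nA <- length(a); nB <- length(b)
    k <- sum(a)
    p <- hypergeomTailP(k, sum(a) + sum(b), nA, nA + nB)
    list(freq_a = mean(a), freq_b = mean(b), n_a = nA, n_b = nB, p = p)
}
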