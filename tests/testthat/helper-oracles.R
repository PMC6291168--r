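## Independent oracles and fixture builders shared across the suite.
## Oracles deliberately use brute-force enumeration or direct formulas,
## never the code paths they check.

ariScore <- function(a, b) {
    tab <- table(a, b)
    n <- sum(tab)
    sc <- function(x) sum(choose(x, 2))
    si <- sc(tab); sa <- sc(rowSums(tab)); sb <- sc(colSums(tab))
    ex <- sa * sb / choose(n, 2)
    (si - ex) / ((sa + sb) / 2 - ex)
}

## exhaustive forward likelihood: sum over all K^T state paths
enumLogLik <- function(bits, pi, A, B) {
    T <- nrow(bits); K <- length(pi)
    emit <- function(k, t)
        prod(ifelse(bits[t, ] == 1, B[k, ], 1 - B[k, ]))
    paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
    tot <- 0
    for (r in seq_len(nrow(paths))) {
        s <- paths[r, ]
        p <- pi[s[1]] * emit(s[1], 1)
        for (t in seq_len(T - 1))
            p <- p * A[s[t], s[t + 1]] * emit(s[t + 1], t + 1)
        tot <- tot + p
    }
    log(tot)
}

## probability of one specific state path
pathProb <- function(bits, pi, A, B, s) {
    T <- nrow(bits)
    emit <- function(k, t)
        prod(ifelse(bits[t, ] == 1, B[k, ], 1 - B[k, ]))
    p <- pi[s[1]] * emit(s[1], 1)
    for (t in seq_len(T - 1))
        p <- p * A[s[t], s[t + 1]] * emit(s[t + 1], t + 1)
    p
}

## exhaustive Viterbi: argmax over all K^T paths
enumViterbi <- function(bits, pi, A, B) {
    T <- nrow(bits); K <- length(pi)
    emit <- function(k, t)
        prod(ifelse(bits[t, ] == 1, B[k, ], 1 - B[k, ]))
    paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
    best <- -Inf; arg <- NULL
    for (r in seq_len(nrow(paths))) {
        s <- paths[r, ]
        p <- pi[s[1]] * emit(s[1], 1)
        for (t in seq_len(T - 1))
            p <- p * A[s[t], s[t + 1]] * emit(s[t + 1], t + 1)
        if (p > best) { best <- p; arg <- s }
    }
    as.integer(arg)
}

## backward-recursion log-likelihood in plain R (independent of the scaled
## C++ forward pass)
backwardLogLik <- function(bits, pi, A, B) {
    T <- nrow(bits); K <- length(pi)
    emit <- function(t)
        vapply(seq_len(K), function(k)
            prod(ifelse(bits[t, ] == 1, B[k, ], 1 - B[k, ])), numeric(1))
    beta <- rep(1, K)
    for (t in rev(seq_len(T - 1)))
        beta <- as.vector(A %*% (emit(t + 1) * beta))
    log(sum(pi * emit(1) * beta))
}

## all-pairs interval overlap counts
bruteOverlap <- function(a, b, minOverlap = 1) {
    ga <- as.data.frame(peaks(a)); gb <- as.data.frame(peaks(b))
    ovl <- function(x, y) {
        sapply(seq_len(nrow(x)), function(i) {
            any(y$seqnames == x$seqnames[i] &
                pmin(y$end, x$end[i]) - pmax(y$start, x$start[i]) + 1 >=
                minOverlap)
        })
    }
    list(ab = sum(ovl(ga, gb)), ba = sum(ovl(gb, ga)))
}

## all-pairs nearest-TSS assignment (ties toward smaller coordinate)
bruteNearestTSS <- function(x, annotation, maxDist = 1e6) {
    gr <- peaks(x)
    tss <- tssSites(annotation)
    tdf <- data.frame(chrom = as.character(seqnames(tss)),
                      pos = start(tss),
                      strand = as.character(strand(tss)),
                      gene = S4Vectors::mcols(tss)$gene_id)
    mid <- (start(gr) + end(gr)) %/% 2
    out <- data.frame(gene_id = rep(NA_character_, length(gr)),
                      distance = rep(NA_real_, length(gr)))
    for (i in seq_along(gr)) {
        sel <- tdf[tdf$chrom == as.character(seqnames(gr))[i], ]
        if (!nrow(sel)) next
        d <- abs(mid[i] - sel$pos)
        if (min(d) > maxDist) next
        sel <- sel[d == min(d), ]
        sel <- sel[order(sel$pos), ]
        out$gene_id[i] <- sel$gene[1]
        out$distance[i] <- if (sel$strand[1] == "+") mid[i] - sel$pos[1]
                           else sel$pos[1] - mid[i]
    }
    out
}

## O(genes x bins) class membership scan
bruteClassGenes <- function(path, annotation, window = 25000) {
    bs <- binSize(path)
    tss <- tssSites(annotation)
    out <- rep(list(character(0)), nStates(path))
    names(out) <- as.character(seq_len(nStates(path)))
    for (i in seq_along(tss)) {
        chrom <- as.character(seqnames(tss))[i]
        p <- statePath(path)[[chrom]]
        if (is.null(p)) next
        tpos <- start(tss)[i]
        for (b in seq_along(p)) {
            binStart <- (b - 1) * bs + 1
            binEnd <- b * bs
            ## any bp of the bin inside [tss - window, tss + window - 1]
            if (binEnd >= tpos - window && binStart <= tpos + window - 1)
                out[[p[b]]] <- c(out[[p[b]]],
                                 S4Vectors::mcols(tss)$gene_id[i])
        }
    }
    lapply(out, unique)
}

## direct hypergeometric upper tail from binomial coefficients
bruteHyperUpper <- function(k, K, n, N) {
    lo <- max(0, K + n - N); hi <- min(K, n)
    kk <- lo:hi
    terms <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
    min(1, sum(terms[kk >= k]))
}

## naive sliding-window canonical k-mer recount (both strands, N skipped)
recountKmers <- function(seqs, k) {
    seqs <- as.character(Biostrings::DNAStringSet(seqs))
    rc <- function(s) {
        map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
        paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
    }
    cnt <- new.env()
    add <- function(w) {
        if (grepl("[^ACGT]", w)) return()
        key <- min(w, rc(w))
        cnt[[key]] <- (if (is.null(cnt[[key]])) 0 else cnt[[key]]) + 1
    }
    for (s in seqs) {
        for (i in seq_len(nchar(s) - k + 1)) add(substr(s, i, i + k - 1))
        s2 <- rc(gsub("[^ACGT]", "N", s))
        for (i in seq_len(nchar(s2) - k + 1)) add(substr(s2, i, i + k - 1))
    }
    out <- unlist(as.list(cnt))
    out[order(names(out))]
}

## random peak set on a toy genome
randomPeakSet <- function(n, chroms = c("chr1", "chr2"), size = 10000,
                          maxWidth = 400, target = "peak") {
    chrom <- sample(chroms, n, replace = TRUE)
    w <- sample.int(maxWidth, n, replace = TRUE) + 20L
    s <- vapply(w, function(wi) sample.int(size - wi, 1L), integer(1))
    PeakSet(target, "siControl",
            GenomicRanges::GRanges(chrom, IRanges::IRanges(s, s + w - 1L),
                                   score = runif(n, 0, 100)))
}

## 4 well-separated planted states for HMM parameter-recovery checks
hmmBenchRates <- function() {
    er <- rbind(c(20, 0.2, 0.2, 0.2, 0.2, 0.2),
                c(0.2, 20, 0.2, 0.2, 0.2, 0.2),
                c(0.2, 0.2, 20, 20, 0.2, 0.2),
                c(0.2, 0.2, 0.2, 0.2, 0.2, 0.2))
    colnames(er) <- c("ERG", "FLI1", "H3K4me3.siControl", "H3K4me3.siEF",
                      "H3K27Ac.siControl", "H3K27Ac.siEF")
    er
}

allPermutations <- function(K) {
    g <- as.matrix(expand.grid(rep(list(seq_len(K)), K)))
    g[apply(g, 1L, function(p) length(unique(p)) == K), , drop = FALSE]
}

## direct, independent evaluation of the five screening criteria on planted
## peaks, ground-truth attenuated regions and the noiseless expression means
bruteScreen <- function(sim, geneMeans, window = 25000) {
    ann <- sim$annotation
    tss <- tssSites(ann)
    mids <- function(ps) {
        gr <- peaks(ps)
        data.frame(chrom = as.character(seqnames(gr)),
                   mid = (start(gr) + end(gr)) %/% 2,
                   start = start(gr), end = end(gr))
    }
    erg <- mids(sim$chromatin$peaks$ERG)
    fli <- mids(sim$chromatin$peaks$FLI1)
    k27 <- mids(sim$chromatin$peaks$H3K27Ac.siControl)
    tr <- as.data.frame(sim$truth$differentialRegionsTrue)
    found <- character(0)
    for (i in seq_along(tss)) {
        chrom <- as.character(seqnames(tss))[i]
        tpos <- start(tss)[i]
        gid <- S4Vectors::mcols(tss)$gene_id[i]
        nearE <- erg[erg$chrom == chrom & abs(erg$mid - tpos) <= window, ]
        nearF <- fli[fli$chrom == chrom & abs(fli$mid - tpos) <= window, ]
        if (!nrow(nearE) || !nrow(nearF)) next
        tf <- rbind(nearE, nearF)
        ## K27Ac peaks overlapping any such TF peak
        hitK <- k27[sapply(seq_len(nrow(k27)), function(j)
            k27$chrom[j] == chrom &&
            any(pmin(k27$end[j], tf$end) - pmax(k27$start[j], tf$start) >= 0)), ]
        if (!nrow(hitK)) next
        ## ... that intersect a ground-truth attenuated region
        red <- any(sapply(seq_len(nrow(hitK)), function(j)
            any(tr$seqnames == hitK$chrom[j] &
                pmin(tr$end, hitK$end[j]) - pmax(tr$start, hitK$start[j]) >= 0)))
        if (!red) next
        if (!gid %in% rownames(geneMeans)) next
        ctrl <- geneMeans[gid, "siControl.3"]
        sE <- geneMeans[gid, "siERG.3"]
        sF <- geneMeans[gid, "siFLI1.3"]
        sC <- geneMeans[gid, "siERG+siFLI1.3"]
        if ((ctrl - sC) / ctrl > 0.7 && sC < sE && sC < sF)
            found <- c(found, gid)
    }
    found
}
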