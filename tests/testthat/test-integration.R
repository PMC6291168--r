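test_that("log-space hypergeometric tails are exact", {
    ## worked table: N = 20, |class| = 5, |cluster| = 4, overlap 4
    expect_equal(hypergeomTailP(4, 5, 4, 20), 5 / 4845, tolerance = 1e-12)

    set.seed(33)
    for (i in 1:200) {
        N <- sample(5:300, 1)
        K <- sample.int(N, 1); n <- sample.int(N, 1)
        lo <- max(0, K + n - N); hi <- min(K, n)
        k <- if (lo == hi) lo else sample(lo:hi, 1)
        expect_equal(hypergeomTailP(k, K, n, N),
                     bruteHyperUpper(k, K, n, N),
                     tolerance = 1e-10)
    }

    ## independent cross-checks: stats::phyper and stats::fisher.test
    expect_equal(hypergeomTailP(17, 40, 30, 120),
                 phyper(16, 40, 80, 30, lower.tail = FALSE),
                 tolerance = 1e-12)
    ft <- fisher.test(matrix(c(17, 23, 13, 67), 2), alternative = "greater")
    expect_equal(hypergeomTailP(17, 40, 30, 120), ft$p.value,
                 tolerance = 1e-7)

    ## monotone decreasing in the overlap for fixed margins
    p <- hypergeomTailP(0:10, 25, 10, 100)
    expect_true(all(diff(p) <= 0))
    expect_equal(p[1], 1)

    expect_error(hypergeomTailP(11, 25, 10, 100), "support")
})

test_that("class-by-cluster Fisher association fills exact 2x2 tables", {
    universe <- sprintf("g%03d", 1:40)
    classes <- list(c5 = universe[1:10], c7 = universe[11:30])
    clusters <- list(`1` = universe[c(1:8, 31:32)], `2` = character(0))
    res <- fisherAssociation(classes, clusters, universe)
    expect_true(all(res$n11 + res$n10 + res$n01 + res$n00 == 40))
    r <- res[res$class == "c5" & res$cluster == "1", ]
    expect_equal(r$n11, 8L)
    expect_equal(r$p, bruteHyperUpper(8, 10, 10, 40), tolerance = 1e-12)
    ## empty cluster: p = 1
    expect_true(all(res$p[res$cluster == "2"] == 1))
    expect_error(fisherAssociation(classes, clusters, character(0)),
                 "empty universe")
})

test_that("differential H3K27Ac calling uses the doubled binomial tail", {
    regs <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(seq(1, by = 2000, length.out = 6), width = 1000))
    cc <- c(100, 200, 200, 150, 180, 170)
    ck <- c(10, 200, 205, 150, 178, 169)
    d <- differentialK27ac(regs, cc, ck, totalControl = 1000,
                           totalKnockdown = 1000)
    mc <- S4Vectors::mcols(d)
    expect_equal(mc$log2fc[1], log2(10 / 100), tolerance = 1e-12)
    expect_equal(mc$p[1], 2 * pbinom(10, 110, 0.5), tolerance = 1e-12)
    expect_equal(mc$direction[1], "decreased")
    expect_true(all(mc$direction[-1] == "unchanged"))
    expect_true(all(mc$q >= mc$p - 1e-15))
    ## BH-adjusted values are monotone in p
    expect_true(all(diff(mc$q[order(mc$p)]) >= -1e-15))

    expect_error(differentialK27ac(regs, rep(0, 6), rep(0, 6)),
                 "zero total")
})

test_that("region counts prorate partial bins", {
    ts <- BinnedTrackSet(200, list(chr1 = cbind(m = c(10, 20, 30))))
    regs <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1, 101, 301), c(200, 300, 600)))
    expect_equal(regionCounts(ts, regs, "m"), c(10, 5 + 10, 10 + 30))
})

test_that("class-gene membership matches the gene x bin scan", {
    set.seed(41)
    for (i in 1:5) {
        path <- new("StatePath",
                    path = list(chr1 = sample.int(4, 500, replace = TRUE),
                                chr2 = sample.int(4, 300, replace = TRUE)),
                    nStates = 4L, binSize = 200L, posterior = NULL)
        genesDf <- data.frame(gene_id = sprintf("g%02d", 1:15),
                              chrom = sample(c("chr1", "chr2", "chr3"), 15,
                                             replace = TRUE),
                              start = sample.int(9e4, 15),
                              strand = sample(c("+", "-"), 15,
                                              replace = TRUE))
        genesDf$end <- genesDf$start + 2000L
        ann <- GenomeAnnotation(genesDf,
            chromSizes = c(chr1 = 1e5, chr2 = 1e5, chr3 = 1e5))
        got <- genesForClass(path, ann, window = 10000)
        want <- bruteClassGenes(path, ann, window = 10000)
        for (cl in names(want))
            expect_setequal(got[[cl]], want[[cl]])
        ## genes on the chromosome with no decoded bins appear nowhere
        onChr3 <- genesDf$gene_id[genesDf$chrom == "chr3"]
        expect_false(any(onChr3 %in% unlist(got)))
    }
})

test_that("the candidate screen flags each criterion independently", {
    ## toy locus: one gene with ERG+FLI1 peaks over a K27Ac peak
    ann <- GenomeAnnotation(
        data.frame(gene_id = c("hit", "noPeak"), chrom = "chr1",
                   start = c(30000, 200000), end = c(32000, 202000),
                   strand = "+"),
        chromSizes = c(chr1 = 3e5))
    tf <- GenomicRanges::GRanges("chr1", IRanges::IRanges(25000, 26000))
    erg <- PeakSet("ERG", peaks = tf)
    fli <- PeakSet("FLI1", peaks = tf)
    k27 <- PeakSet("H3K27Ac", peaks = GenomicRanges::GRanges("chr1",
        IRanges::IRanges(24500, 26500)))
    decRegion <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(24500, 26500))
    mkDiff <- function(direction) {
        g <- decRegion
        S4Vectors::mcols(g)$direction <- direction
        g
    }
    gm <- matrix(rep(c(1000, 500, 450, 299, 1000, 500, 450, 299,
                       1000, 900, 900, 950, 1000, 900, 900, 950),
                     each = 1), nrow = 2, byrow = TRUE,
                 dimnames = list(c("hit", "noPeak"),
                                 as.vector(outer(c("siControl", "siERG",
                                                   "siFLI1",
                                                   "siERG+siFLI1"),
                                                 c("3", "7"), paste,
                                                 sep = "."))))
    scr <- candidateScreen(erg, fli, k27, mkDiff("decreased"), gm, ann)
    hit <- scr[scr$gene_id == "hit", ]
    expect_true(hit$is_candidate)
    expect_true(all(unlist(hit[, 2:6])))
    expect_false(scr[scr$gene_id == "noPeak", "has_upstream_peak"])

    ## failing exactly criterion (c): differential region not decreased
    scrC <- candidateScreen(erg, fli, k27, mkDiff("unchanged"), gm, ann)
    hitC <- scrC[scrC$gene_id == "hit", ]
    expect_false(hitC$is_candidate)
    expect_false(hitC$k27ac_reduced)
    expect_true(hitC$has_upstream_peak && hitC$peak_in_k27ac &&
                hitC$expr_reduced_70 && hitC$combo_exceeds_singles)

    ## expression boundary: >70% reduction is strict
    gm300 <- gm; gm300["hit", "siERG+siFLI1.3"] <- 300
    scr300 <- candidateScreen(erg, fli, k27, mkDiff("decreased"), gm300,
                              ann)
    expect_false(scr300[scr300$gene_id == "hit", "expr_reduced_70"])

    ## either-TF mode
    scrE <- candidateScreen(erg, PeakSet("FLI1"), k27, mkDiff("decreased"),
                            gm, ann, tfMode = "either")
    expect_true(scrE[scrE$gene_id == "hit", "has_upstream_peak"])
    scrB <- candidateScreen(erg, PeakSet("FLI1"), k27, mkDiff("decreased"),
                            gm, ann, tfMode = "both")
    expect_false(scrB[scrB$gene_id == "hit", "has_upstream_peak"])

    ## gene missing from the expression matrix
    expect_warning(
        scrM <- candidateScreen(erg, fli, k27, mkDiff("decreased"),
                                gm["noPeak", , drop = FALSE], ann),
        "absent")
    expect_false(scrM[scrM$gene_id == "hit", "expr_reduced_70"])

    ## is_candidate is the intersection of the single-criterion gene sets
    sets <- lapply(scr[, 2:6], function(f) scr$gene_id[f])
    expect_setequal(Reduce(intersect, sets), scr$gene_id[scr$is_candidate])
})

test_that("planted attenuated regions are recovered from study data", {
    cfg <- simulationConfig(seed = 29)
    sim <- simulateStudy(cfg)
    k27c <- sim$chromatin$peaks$H3K27Ac.siControl
    regs <- GenomicRanges::reduce(peaks(k27c))
    d <- differentialK27ac(regs,
        regionCounts(sim$chromatin$control, regs, "H3K27Ac"),
        regionCounts(sim$chromatin$knockdown, regs, "H3K27Ac"))
    dec <- d[S4Vectors::mcols(d)$direction == "decreased"]
    tr <- sim$truth$differentialRegionsTrue
    ## every call overlaps a planted region and most planted regions with a
    ## clean (unmerged) acetylation peak are found
    expect_true(all(GenomicRanges::countOverlaps(dec, tr) > 0))
    expect_gte(sum(GenomicRanges::countOverlaps(tr, dec) > 0) / length(tr),
               0.6)
})
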