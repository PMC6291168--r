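## fixture: a tiny KnockdownExpression built in code
makeExpr <- function(vals, nrep = 1L) {
    ## vals: probe x 8 matrix of group-level values, replicated nrep times
    groups <- expand.grid(treatment = c("siControl", "siERG", "siFLI1",
                                        "siERG+siFLI1"),
                          day = c("3", "7"), stringsAsFactors = FALSE)
    meta <- groups[rep(seq_len(8), each = nrep), ]
    meta$replicate <- rep(seq_len(nrep), times = 8)
    meta$sample <- sprintf("s%02d", seq_len(nrow(meta)))
    m <- vals[, rep(seq_len(8), each = nrep), drop = FALSE]
    colnames(m) <- meta$sample
    p2g <- setNames(rownames(vals), rownames(vals))
    KnockdownExpression(m, p2g, meta)
}

groupCols <- as.vector(outer(c("siControl", "siERG", "siFLI1",
                               "siERG+siFLI1"), c("3", "7"), paste,
                             sep = "."))

test_that("group means average replicates on the linear scale", {
    v <- matrix(1:8 * 100, 1, 8, dimnames = list("p1", NULL))
    x <- makeExpr(v)
    gm <- groupMeans(x)
    expect_equal(unname(gm["p1", ]), as.numeric(v))   # 1 rep: raw values

    x2 <- makeExpr(v, nrep = 2L)
    a <- SummarizedExperiment::assay(x2, "signal")
    a["p1", c("s01", "s02")] <- c(100, 300)
    x2 <- KnockdownExpression(a, setNames("p1", "p1"),
                              as.data.frame(SummarizedExperiment::colData(x2)) |>
                                  (\(d) { d$sample <- rownames(d); d })())
    expect_equal(unname(groupMeans(x2)["p1", "siControl.3"]), 200)

    ## a missing group is an error naming the group
    a3 <- a[, 1:14, drop = FALSE]    # drops the siERG+siFLI1 day-7 group
    cd <- as.data.frame(SummarizedExperiment::colData(x2))[1:14, ]
    cd$sample <- rownames(cd)
    x3 <- KnockdownExpression(a3, setNames("p1", "p1"), cd)
    expect_error(groupMeans(x3), "siERG\\+siFLI1, day 7")
})

test_that("probe filters apply inclusive signal and CV thresholds", {
    base <- c(100, 120, 90, 110, 100, 95, 105, 100)
    gm <- rbind(
        low = base * 299.9 / max(base),        # max group mean 299.9
        const = rep(1000, 8),                  # CV = 0
        good = c(1000, 100, 100, 100, 100, 100, 100, 100),
        zero = rep(0, 8))
    colnames(gm) <- groupCols
    expect_identical(filterProbes(gm), "good")

    ## boundary: inclusive on both criteria (threshold set to the probe's
    ## own CV; scaling cannot change the CV)
    v <- c(rep(300, 4), rep(110, 4))
    gmB <- rbind(b = v); colnames(gmB) <- groupCols
    cv0 <- sd(v) / mean(v)
    expect_identical(filterProbes(gmB, minSignal = 300, minCV = cv0), "b")
    expect_identical(filterProbes(gmB, minSignal = 300.0001, minCV = cv0),
                     character(0))
    expect_identical(filterProbes(gmB, minSignal = 300,
                                  minCV = cv0 + 1e-12), character(0))
})

test_that("probe filtering is order-independent and idempotent", {
    set.seed(2)
    gm <- matrix(exp(rnorm(400, 5, 2)), 50, 8,
                 dimnames = list(sprintf("p%02d", 1:50), groupCols))
    keep <- filterProbes(gm)
    perm <- sample.int(50)
    expect_setequal(filterProbes(gm[perm, ]), keep)
    expect_setequal(filterProbes(gm[keep, , drop = FALSE]), keep)
})

test_that("probe collapse keeps the largest-sum probe with stable ties", {
    gm <- rbind(pa = rep(125, 8), pb = rep(250, 8), pc = rep(99, 8),
                pz = rep(125, 8))
    colnames(gm) <- groupCols
    p2g <- c(pa = "g1", pb = "g1", pc = "g2", pz = "g3")
    out <- collapseProbes(rownames(gm), gm, p2g)
    expect_equal(attr(out, "probe")[["g1"]], "pb")    # 2000 beats 1000
    expect_equal(attr(out, "probe")[["g2"]], "pc")    # single probe

    p2gTie <- c(pa = "g1", pz = "g1")
    expect_warning(
        outT <- collapseProbes(c("pz", "pa"), gm, p2gTie), "tie.*pa")
    expect_equal(attr(outT, "probe")[["g1"]], "pa")
})

test_that("clustering Z-scores rows and recovers separable structure", {
    set.seed(4)
    up <- c(1, 1, 2, 2, 1, 1, 2, 2)
    blockA <- matrix(rep(100 * up, 10), 10, byrow = TRUE) +
        matrix(rnorm(80, 0, 4), 10)
    blockB <- matrix(rep(100 * rev(up), 10), 10, byrow = TRUE) +
        matrix(rnorm(80, 0, 4), 10)
    m <- rbind(blockA, blockB)
    dimnames(m) <- list(sprintf("g%02d", 1:20), groupCols)
    cl <- clusterGenes(m, kMajor = 2)
    z <- cl@zscores
    expect_true(all(abs(rowMeans(z)) < 1e-12))
    expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-12))
    expect_equal(ariScore(clusterLabels(cl), rep(1:2, each = 10)), 1)

    ## invariances: gene order and uniform scaling
    perm <- sample.int(20)
    clP <- clusterGenes(m[perm, ], kMajor = 2)
    expect_equal(ariScore(clusterLabels(clP)[rownames(m)],
                          clusterLabels(cl)), 1)
    clS <- clusterGenes(m * 7, kMajor = 2)
    expect_identical(clusterLabels(clS), clusterLabels(cl))

    mz <- m; mz[1, ] <- 5
    expect_error(clusterGenes(mz, 2), "zero-variance")
})

test_that("recutCluster splits one cluster and renumbers by size", {
    set.seed(6)
    prof <- rbind(c(1, 1, 1, 1, 5, 5, 5, 5),
                  c(5, 5, 5, 5, 1, 1, 1, 1),
                  c(5, 1, 5, 1, 5, 1, 5, 1))
    m <- prof[c(rep(1, 8), rep(2, 6), rep(3, 4)), ] * 100 +
        matrix(rnorm(144, 0, 2), 18)
    dimnames(m) <- list(sprintf("g%02d", 1:18), groupCols)
    cl2 <- clusterGenes(m, kMajor = 2)   # merges two of the three blocks
    big <- as.integer(names(which.max(table(clusterLabels(cl2)))))
    cl3 <- recutCluster(cl2, m, cluster = big, k2 = 2)
    expect_equal(max(clusterLabels(cl3)), 3L)
    expect_equal(ariScore(clusterLabels(cl3),
                          c(rep(1, 8), rep(2, 6), rep(3, 4))), 1)
})

test_that("day-3 regulation templates classify canonical profiles", {
    cand <- list(I    = c(100, 500, 150, 600),
                 II   = c(100, 150, 500, 600),
                 III  = c(100, 500, 500, 700),
                 IV   = c(100, 600, 100, 300),
                 V    = c(100, 500, 100, 100),
                 VI   = c(300, 100, 600, 300),
                 VII  = c(600, 150, 450, 100),
                 VIII = c(600, 450, 150, 100),
                 other = c(100, 100, 100, 100))
    m <- do.call(rbind, cand)
    mat <- cbind(m, m)
    dimnames(mat) <- list(names(cand), groupCols)
    pa <- classifyPatterns(mat)
    expect_identical(unname(patternLabels(pa)), names(cand))
    expect_error(classifyPatterns(mat, delta = 0), "delta")
})

test_that("planted regulation patterns are recovered exactly without noise", {
    cfg <- simulationConfig(seed = 17, noiseScale = 0)
    ann <- simulateGenome(cfg)
    ex <- simulateExpression(cfg, ann)
    gm <- groupMeans(ex$expression)
    keep <- filterProbes(gm)
    gmat <- collapseProbes(keep, gm, ex$truth$probeToGene)
    pa <- classifyPatterns(gmat)
    expect_identical(unname(patternLabels(pa)),
                     unname(ex$truth$patternLabelsTrue[rownames(gmat)]))
    ## the opposing-regulation group comes out as template VI
    vi <- names(ex$truth$clusterLabelsTrue)[
        ex$truth$clusterLabelsTrue == "opposing"]
    expect_true(all(patternLabels(pa)[intersect(vi, rownames(gmat))] ==
                    "VI"))
})

test_that("planted clusters are recovered with noise (ARI >= 0.9)", {
    cfg <- simulationConfig(seed = 23, noiseScale = 0.6)
    ann <- simulateGenome(cfg)
    ex <- simulateExpression(cfg, ann)
    gm <- groupMeans(ex$expression)
    keep <- filterProbes(gm)
    gmat <- collapseProbes(keep, gm, ex$truth$probeToGene)
    cl <- clusterGenes(gmat, kMajor = 6)
    expect_gte(ariScore(clusterLabels(cl),
                        ex$truth$clusterLabelsTrue[rownames(gmat)]), 0.9)
})
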