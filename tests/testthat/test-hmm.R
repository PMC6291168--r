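## small helper: wrap a list of bit matrices as a BinaryTrackSet
asBits <- function(...) {
    mats <- list(...)
    names(mats) <- paste0("chr", seq_along(mats))
    mats <- lapply(mats, function(m) {
        colnames(m) <- paste0("mark", seq_len(ncol(m))); m })
    new("BinaryTrackSet", binSize = 200L,
        marks = colnames(mats[[1]]), counts = mats)
}

test_that("Poisson-tail binarization matches the tail formula", {
    ## lambda = 1: count 10 has tail ~1.1e-7 <= 1e-4 -> bit 1; count 0 -> 0
    v1 <- c(rep(0, 999), 10)           # genome-wide mean ~0.01? keep lambda
    cnt <- matrix(c(rep(1, 990), rep(2, 9), 10), ncol = 1,
                  dimnames = list(NULL, "m"))   # mean ~1.018
    ts <- BinnedTrackSet(200, list(chr1 = cnt))
    bits <- binarizeTracks(ts)
    lam <- mean(cnt)
    expect_lte(ppois(10 - 1, lam, lower.tail = FALSE), 1e-4)
    expect_equal(unname(trackCounts(bits)$chr1[1000, "m"]), 1)
    expect_true(all(trackCounts(bits)$chr1[1:999, "m"] == 0))

    ## lambda = 5, count 5: tail ~0.56 -> bit 0
    cnt5 <- matrix(rpois(2000, 5), ncol = 1, dimnames = list(NULL, "m"))
    cnt5[1] <- 5
    ts5 <- BinnedTrackSet(200, list(chr1 = cnt5))
    b5 <- binarizeTracks(ts5)
    expect_equal(unname(trackCounts(b5)$chr1[1, "m"]), 0)
})

test_that("a one-state model has closed-form parameters", {
    set.seed(1)
    bits <- asBits(matrix(rbinom(600, 1, c(0.2, 0.7, 0.05)),
                          ncol = 3, byrow = TRUE))
    m <- trainHMM(bits, K = 1, nRestarts = 1, seed = 1)
    freq <- colMeans(trackCounts(bits)[[1]])
    expect_equal(unname(emissionProb(m)[1, ]), unname(freq),
                 tolerance = 1e-6)
    expect_equal(transMat(m), matrix(1, 1, 1))
})

test_that("forward log-likelihood equals exhaustive path enumeration", {
    set.seed(12)
    for (i in 1:10) {
        K <- sample(2:3, 1); M <- sample(1:3, 1); T <- sample(4:6, 1)
        pi <- { x <- rgamma(K, 1); x / sum(x) }
        A <- t(apply(matrix(rgamma(K * K, 1), K), 1,
                     function(r) r / sum(r)))
        B <- matrix(runif(K * M, 0.05, 0.95), K, M)
        bits <- matrix(rbinom(T * M, 1, 0.5), T, M)
        model <- StateModel(pi, A, B)
        bt <- asBits(bits)
        expect_equal(hmmLogLik(model, bt), enumLogLik(bits, pi, A, B),
                     tolerance = 1e-9)
        ## independent backward-recursion route agrees too
        expect_equal(hmmLogLik(model, bt), backwardLogLik(bits, pi, A, B),
                     tolerance = 1e-9)
    }
})

test_that("Viterbi decoding equals exhaustive argmax over paths", {
    set.seed(23)
    for (i in 1:10) {
        K <- 2; M <- 2; T <- 5
        pi <- { x <- rgamma(K, 1); x / sum(x) }
        A <- t(apply(matrix(rgamma(K * K, 1), K), 1,
                     function(r) r / sum(r)))
        B <- matrix(runif(K * M, 0.05, 0.95), K, M)
        bits <- matrix(rbinom(T * M, 1, 0.5), T, M)
        model <- StateModel(pi, A, B)
        got <- statePath(decodeStates(model, asBits(bits)))[[1]]
        best <- enumViterbi(bits, pi, A, B)
        ## equally probable paths can tie; compare achieved probability
        expect_equal(pathProb(bits, pi, A, B, got),
                     pathProb(bits, pi, A, B, best), tolerance = 1e-9)
    }
})

test_that("deterministic emissions decode to the unique consistent path", {
    B <- rbind(c(1, 0), c(0, 1))
    model <- StateModel(c(0.5, 0.5), matrix(0.5, 2, 2), B)
    bits <- matrix(c(1, 0, 0, 1, 1,
                     0, 1, 1, 0, 0), ncol = 2)
    got <- statePath(decodeStates(model, asBits(bits)))[[1]]
    expect_identical(got, c(1L, 2L, 2L, 1L, 1L))

    ## K = 1 decodes every bin to state 1
    m1 <- StateModel(1, matrix(1, 1, 1), matrix(0.5, 1, 2))
    expect_true(all(statePath(decodeStates(m1, asBits(bits)))[[1]] == 1L))
})

test_that("Baum-Welch log-likelihood is monotone and keeps stochasticity", {
    set.seed(3)
    cfg <- simulationConfig(seed = 3, nChroms = 1, chromLength = 4e5,
                            emissionRates = hmmBenchRates(),
                            stickiness = 0.95, nGenes = 20,
                            nProbes = 30, clusterSpec = list())
    ann <- simulateGenome(cfg)
    ch <- simulateChromatin(cfg, ann)
    bits <- binarizeTracks(ch$combined)
    m <- trainHMM(bits, K = 4, nRestarts = 2, seed = 5)
    tr <- attr(m, "llTrace")
    expect_true(all(diff(tr) > -1e-6 * abs(tr[-length(tr)])))
    expect_true(all(abs(rowSums(transMat(m)) - 1) < 1e-10))
    expect_lt(abs(sum(startProb(m)) - 1), 1e-10)
    expect_true(all(emissionProb(m) >= 0 & emissionProb(m) <= 1))
})

test_that("permuting the initialization permutes the learned states", {
    set.seed(8)
    cfg <- simulationConfig(seed = 8, nChroms = 1, chromLength = 2e5,
                            emissionRates = hmmBenchRates(),
                            stickiness = 0.95, nGenes = 20,
                            nProbes = 30, clusterSpec = list())
    ann <- simulateGenome(cfg)
    ch <- simulateChromatin(cfg, ann)
    bits <- binarizeTracks(ch$combined)
    K <- 3
    init <- list(pi = rep(1 / K, K),
                 A = matrix(c(.8, .1, .1, .1, .8, .1, .1, .1, .8), K,
                            byrow = TRUE),
                 B = matrix(runif(K * 6, 0.1, 0.9), K))
    perm <- c(3L, 1L, 2L)
    initP <- list(pi = init$pi[perm], A = init$A[perm, perm],
                  B = init$B[perm, ])
    m1 <- trainHMM(bits, K = K, init = init)
    m2 <- trainHMM(bits, K = K, init = initP)
    expect_equal(m1@logLik, m2@logLik, tolerance = 1e-6)
    ## learned parameters agree up to the same permutation
    expect_equal(emissionProb(m2), emissionProb(m1)[perm, ],
                 tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("degenerate inputs are rejected", {
    bits <- asBits(matrix(rbinom(30, 1, .5), ncol = 3))
    expect_error(trainHMM(bits, K = 100), "exceeds")
    notBits <- BinnedTrackSet(200, list(chr1 = matrix(1:10, ncol = 1)))
    expect_error(trainHMM(notBits, K = 2), "BinaryTrackSet")
})

test_that("sparse quiescent states merge into one class, stably renumbered", {
    ## hand-built decoded path over 3 states: state 3 is rare and silent
    path <- new("StatePath",
                path = list(chr1 = c(rep(1L, 500), rep(2L, 480),
                                     rep(3L, 2), rep(2L, 18))),
                nStates = 3L, binSize = 200L, posterior = NULL)
    B <- rbind(c(.9, .1), c(.1, .8), c(.01, .02))
    model <- StateModel(c(.4, .4, .2),
                        matrix(c(.9, .05, .05, .05, .9, .05, .3, .3, .4),
                               3, byrow = TRUE), B)
    out <- mergeSparseStates(model, path)
    expect_equal(nStates(out$model), 3L)   # merged class replaces state 3
    ## state with higher occupancy gets class 1
    expect_equal(statePath(out$path)$chr1[1], 1L)
    ## bin-to-class mapping is a relabeling of the original
    expect_equal(length(unique(paste(path@path$chr1,
                                     statePath(out$path)$chr1))), 3L)

    ## two silent states merge into a single class
    path2 <- new("StatePath",
                 path = list(chr1 = c(rep(1L, 996), 2L, 3L, 4L, 4L)),
                 nStates = 4L, binSize = 200L, posterior = NULL)
    B2 <- rbind(c(.9, .9), c(.01, .01), c(.02, .01), c(.8, .1))
    model2 <- StateModel(rep(.25, 4),
                         matrix(.25, 4, 4), B2)
    out2 <- mergeSparseStates(model2, path2)
    expect_equal(nStates(out2$model), 3L)  # 4 -> merged(2,3) + kept 1,4
    merged <- statePath(out2$path)$chr1[c(997, 998)]
    expect_equal(merged[1], merged[2])     # both silent states -> one class
    expect_equal(merged[1], 3L)            # quiescent class is last

    ## no state below the floor: unchanged
    out3 <- mergeSparseStates(model, path, occupancyFloor = 1e-6)
    expect_identical(out3$model, model)
    expect_identical(out3$path, path)

    expect_error(mergeSparseStates(model2, path2, occupancyFloor = 2,
                                   emissionCeiling = 2), "all states")
})

test_that("planted states are recovered from binarized tracks", {
    cfg <- simulationConfig(seed = 14, nChroms = 1, chromLength = 1e6,
                            emissionRates = hmmBenchRates(),
                            stickiness = 0.95, nGenes = 50,
                            nProbes = 75, clusterSpec = list())
    ann <- simulateGenome(cfg)
    ch <- simulateChromatin(cfg, ann)
    bits <- binarizeTracks(ch$combined)
    m <- trainHMM(bits, K = 4, nRestarts = 3, seed = 2)
    dec <- decodeStates(m, bits)
    truth <- ch$truth$statePathTrue[[1]]
    got <- statePath(dec)[[1]]
    acc <- max(apply(allPermutations(4), 1,
                     function(p) mean(p[truth] == got)))
    expect_gte(acc, 0.9)
    ## posterior decoding agrees with Viterbi on the vast majority of bins
    post <- statePath(decodeStates(m, bits, method = "posterior"))[[1]]
    expect_gte(mean(post == got), 0.95)
})
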