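## Chromatin-state segmentation: Poisson-tail binarization of binned ChIP
## signal, a multivariate Bernoulli-emission HMM trained by Baum-Welch
## (each chromosome an independent observation sequence), Viterbi/posterior
## decoding, and merging of near-empty states.

.EMIT_EPS <- 1e-6

#' Binarize binned ChIP signal against a Poisson background
#'
#' For each mark, the background rate `lambda` is the genome-wide mean count
#' per bin; a bin is called present (bit 1) when the upper-tail Poisson
#' probability `P(X >= c | lambda)` is at most `pThreshold`.  Non-integer
#' (prorated) counts are handled through `ceiling(c) - 1` in the tail
#' computation.  A mark with `lambda = 0` yields all-zero bits with a
#' warning.
#'
#' @param tracks a [BinnedTrackSet-class].
#' @param pThreshold upper-tail significance threshold (default `1e-4`).
#' @return A [BinaryTrackSet-class] of the same shape.
#' @export
binarizeTracks <- function(tracks, pThreshold = 1e-4) {
    cnt <- trackCounts(tracks)
    total <- Reduce(`+`, lapply(cnt, colSums))
    nb <- sum(vapply(cnt, nrow, integer(1)))
    lambda <- total / nb
    if (any(lambda == 0))
        warning("mark(s) with zero background rate: ",
                paste(marks(tracks)[lambda == 0], collapse = ", "),
                "; all bits 0", call. = FALSE)
    bits <- lapply(cnt, function(m) {
        b <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
        for (j in seq_len(ncol(m))) {
            if (lambda[j] == 0) next
            tail <- ppois(ceiling(m[, j]) - 1, lambda[j],
                          lower.tail = FALSE)
            b[, j] <- as.numeric(tail <= pThreshold)
        }
        b
    })
    new("BinaryTrackSet", binSize = binSize(tracks), marks = marks(tracks),
        counts = bits)
}

## per-bin emission likelihoods P(x_t | state) for a bit matrix (T x M)
.emissionLik <- function(bits, B, log = FALSE) {
    ## clamp log(0) to a large negative finite value so that deterministic
    ## emissions (B = 0 or 1) stay well-defined through the matrix products
    ## (0 * -Inf would be NaN); exp(-1e10) underflows to exactly 0.
    lB <- pmax(log(B), -1e10)        # K x M
    l1mB <- pmax(log1p(-B), -1e10)
    lres <- tcrossprod(bits, lB) + tcrossprod(1 - bits, l1mB)
    if (log) lres else exp(lres)
}

.checkBits <- function(bits) {
    if (!is(bits, "BinaryTrackSet"))
        stop("bits must be a BinaryTrackSet", call. = FALSE)
}

#' Forward log-likelihood of binarized data under a StateModel
#'
#' @param model a [StateModel-class].
#' @param bits a [BinaryTrackSet-class]; each chromosome is an independent
#'   observation sequence.
#' @return Total log-likelihood summed over chromosomes.
#' @export
hmmLogLik <- function(model, bits) {
    .checkBits(bits)
    sum(vapply(trackCounts(bits), function(x) {
        em <- .emissionLik(x, emissionProb(model))
        .fb_scaled(em, startProb(model), transMat(model))$loglik
    }, numeric(1)))
}

## one EM run from an explicit initial model
.emRun <- function(bitList, pi, A, B, tol, maxIter) {
    K <- length(pi)
    llTrace <- numeric(0)
    llPrev <- -Inf
    for (iter in seq_len(maxIter)) {
        ll <- 0
        gammaSum <- matrix(0, K, ncol(B))
        gammaTot <- numeric(K)
        xiSum <- matrix(0, K, K)
        piNum <- numeric(K)
        for (x in bitList) {
            em <- .emissionLik(x, B)
            fb <- .fb_scaled(em, pi, A)
            ll <- ll + fb$loglik
            gammaSum <- gammaSum + crossprod(fb$gamma, x)
            gammaTot <- gammaTot + colSums(fb$gamma)
            xiSum <- xiSum + fb$xi
            piNum <- piNum + fb$gamma[1, ]
        }
        llTrace <- c(llTrace, ll)
        if (is.finite(llPrev) && abs(ll - llPrev) < tol) break
        llPrev <- ll
        ## M-step
        pi <- piNum / sum(piNum)
        rs <- rowSums(xiSum)
        for (k in seq_len(K))
            A[k, ] <- if (rs[k] > 0) xiSum[k, ] / rs[k] else rep(1 / K, K)
        B <- gammaSum / gammaTot
        B[gammaTot == 0, ] <- 0.5
        B <- pmin(pmax(B, .EMIT_EPS), 1 - .EMIT_EPS)
    }
    list(pi = pi, A = A, B = B, logLik = llTrace[length(llTrace)],
         llTrace = llTrace, iterations = length(llTrace))
}

#' Train a Bernoulli-emission HMM by Baum-Welch
#'
#' Fits a K-state hidden Markov model with independent Bernoulli emissions
#' per mark to binarized chromatin tracks.  Each chromosome is treated as an
#' independent observation sequence (chromosome boundaries break the chain).
#' The forward-backward recursions use per-step scaling, which is exactly
#' equivalent to log-space computation; the reported log-likelihood is the
#' sum of log scaling constants.  Of `nRestarts` random initializations
#' (emissions perturbed around the empirical mark frequencies, sticky-uniform
#' transitions), the run with the highest final log-likelihood is returned.
#' The fit is deterministic given `seed`.
#'
#' @param bits a [BinaryTrackSet-class].
#' @param K number of states (default 16).
#' @param nRestarts number of random restarts (default 5).
#' @param seed integer seed controlling initialization.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations per restart.
#' @param init optional explicit initialization: a list with elements
#'   `pi`, `A`, `B`; when given, a single EM run starts from it (no
#'   restarts).
#' @return A [StateModel-class]; attribute `"llTrace"` carries the
#'   per-iteration log-likelihoods of the winning run.
#' @export
trainHMM <- function(bits, K = 16L, nRestarts = 5L, seed = 1L,
                     tol = 1e-4, maxIter = 200L, init = NULL) {
    .checkBits(bits)
    bitList <- trackCounts(bits)
    totBins <- sum(vapply(bitList, nrow, integer(1)))
    if (K > totBins)
        stop("K exceeds the total number of bins", call. = FALSE)
    if (K < 1L) stop("K must be >= 1", call. = FALSE)

    if (!is.null(init)) {
        runs <- list(.emRun(bitList, init$pi, init$A, init$B, tol, maxIter))
    } else {
        freq <- Reduce(`+`, lapply(bitList, colSums)) / totBins
        runs <- lapply(seq_len(nRestarts), function(r) {
            set.seed(seed + r - 1L)
            B0 <- matrix(rep(freq, each = K), K, length(freq)) +
                matrix(runif(K * length(freq), -0.25, 0.25), K)
            B0 <- pmin(pmax(B0, 0.01), 0.99)
            A0 <- matrix(0.1 / max(K - 1, 1), K, K)
            diag(A0) <- if (K > 1) 0.9 else 1
            .emRun(bitList, rep(1 / K, K), A0, B0, tol, maxIter)
        })
    }
    best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "logLik"))]]
    model <- StateModel(best$pi, best$A, best$B, marks = marks(bits),
                        logLik = best$logLik)
    attr(model, "llTrace") <- best$llTrace
    model
}

#' Decode a per-bin state path
#'
#' Viterbi decoding (log-space, default) or per-bin posterior (maximum
#' marginal probability) decoding of binarized tracks under a trained model.
#'
#' @param model a [StateModel-class].
#' @param bits a [BinaryTrackSet-class] with the model's marks.
#' @param method `"viterbi"` or `"posterior"`.
#' @return A [StatePath-class]; for `method = "posterior"` the `posterior`
#'   slot carries the per-bin state probabilities.
#' @export
decodeStates <- function(model, bits, method = c("viterbi", "posterior")) {
    method <- match.arg(method)
    .checkBits(bits)
    if (!identical(marks(model), marks(bits)))
        stop("model and bits disagree on marks", call. = FALSE)
    B <- emissionProb(model)
    if (method == "viterbi") {
        lA <- log(transMat(model))
        lpi <- log(startProb(model))
        path <- lapply(trackCounts(bits), function(x)
            .viterbi_path(.emissionLik(x, B, log = TRUE), lpi, lA))
        post <- NULL
    } else {
        post <- lapply(trackCounts(bits), function(x) {
            fb <- .fb_scaled(.emissionLik(x, B), startProb(model),
                             transMat(model))
            fb$gamma
        })
        path <- lapply(post, function(g) as.integer(max.col(g)))
        names(path) <- names(trackCounts(bits))
    }
    new("StatePath", path = path, nStates = nStates(model),
        binSize = binSize(bits), posterior = post)
}

#' Merge near-empty states into a single quiescent class
#'
#' States whose genome occupancy is below `occupancyFloor` *and* whose
#' maximum emission probability is below `emissionCeiling` are combined into
#' one quiescent class (occupancy-weighted average of their parameters);
#' remaining classes are renumbered stably by descending occupancy, with the
#' merged quiescent class placed last.  With no state below the floor the
#' input is returned unchanged.
#'
#' @param model a [StateModel-class].
#' @param path the matching decoded [StatePath-class].
#' @param occupancyFloor occupancy fraction below which a state is a merge
#'   candidate (default 0.005).
#' @param emissionCeiling maximum emission probability a merge candidate may
#'   have (default 0.05).
#' @return `list(model = <StateModel>, path = <StatePath>)` with merged and
#'   renumbered class ids.
#' @export
mergeSparseStates <- function(model, path, occupancyFloor = 0.005,
                              emissionCeiling = 0.05) {
    K <- nStates(model)
    labels <- unlist(path@path, use.names = FALSE)
    occ <- tabulate(labels, nbins = K) / length(labels)
    sparse <- which(occ < occupancyFloor &
                    apply(emissionProb(model), 1L, max) < emissionCeiling)
    if (length(sparse) == 0L)
        return(list(model = model, path = path))
    if (length(sparse) == K)
        stop("all states would be merged", call. = FALSE)

    keep <- setdiff(seq_len(K), sparse)
    keep <- keep[order(occ[keep], decreasing = TRUE)]
    newK <- length(keep) + 1L
    ## map old state id -> new class id; merged class is last
    remap <- integer(K)
    remap[keep] <- seq_along(keep)
    remap[sparse] <- newK

    w <- occ
    w[w == 0] <- 1e-12   # weight degenerate empty states equally
    aggRows <- c(as.list(keep), list(sparse))
    pi0 <- startProb(model); A0 <- transMat(model); B0 <- emissionProb(model)
    piN <- vapply(aggRows, function(i) sum(pi0[i]), numeric(1))
    BN <- t(vapply(aggRows, function(i)
        colSums(B0[i, , drop = FALSE] * w[i]) / sum(w[i]),
        numeric(ncol(B0))))
    AN <- matrix(0, newK, newK)
    for (a in seq_len(newK)) {
        i <- aggRows[[a]]
        wi <- w[i] / sum(w[i])
        for (b in seq_len(newK)) {
            j <- aggRows[[b]]
            AN[a, b] <- sum(wi * rowSums(A0[i, j, drop = FALSE]))
        }
    }
    AN <- AN / rowSums(AN)
    piN <- piN / sum(piN)

    newPath <- lapply(path@path, function(p) remap[p])
    names(newPath) <- names(path@path)
    list(model = StateModel(piN, AN, BN, marks = marks(model),
                            logLik = NA_real_),
         path = new("StatePath", path = newPath, nStates = newK,
                    binSize = path@binSize, posterior = NULL))
}
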