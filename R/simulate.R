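## Seeded synthetic-data generator.  Emulates the study design: a small
## multi-chromosome genome; a hidden chromatin-state path from a sticky
## Markov chain emitting Poisson counts per mark per 200-bp bin for six
## tracks (ERG, FLI1, H3K4me3 x2 conditions, H3K27Ac x2 conditions); ChIP
## peak sets as maximal runs of emitting states; and an 8-group (4 siRNA
## treatments x 2 days) expression matrix with planted cluster, pattern and
## candidate-gene structure.  Everything is deterministic given the seed.

.MARKS6 <- c("ERG", "FLI1", "H3K4me3.siControl", "H3K4me3.siEF",
             "H3K27Ac.siControl", "H3K27Ac.siEF")

#' Default per-state emission rates
#'
#' A 16-state emission-rate matrix (Poisson mean counts per 200-bp bin per
#' mark).  Signal states: an EC enhancer (ERG + FLI1 + H3K27Ac, acetylation
#' attenuated 10-fold after combined knockdown, emulating the near-complete
#' loss seen at EC-specific enhancers), promoters with and without
#' TF binding, TF-bound sites without acetylation, single-TF sites, gained
#' mesenchymal enhancers/promoters (H3K27Ac/H3K4me3 appearing after
#' knockdown) and a constitutive enhancer.  The remaining states are
#' near-silent variants so that, with the uniform stationary distribution of
#' the sticky chain, signal states occupy a realistically small share of
#' the genome.
#'
#' @return 16 x 6 numeric matrix (states x marks).
#' @export
defaultEmissionRates <- function() {
    m <- rbind(
        EC_enhancer     = c(20,  20,  0.1, 0.1, 20,  2),
        EC_promoter     = c(15,  15,  20,  20,  15,  15),
        promoter        = c(0.1, 0.1, 20,  20,  12,  12),
        TF_bound        = c(18,  18,  0.1, 0.1, 2,   1),
        ERG_only        = c(15,  0.2, 0.1, 0.1, 1,   0.5),
        FLI1_only       = c(0.2, 15,  0.1, 0.1, 1,   0.5),
        mes_enhancer    = c(0.1, 0.1, 0.1, 6,   1,   18),
        gained_promoter = c(0.1, 0.1, 2,   18,  1,   10),
        const_enhancer  = c(0.1, 0.1, 0.5, 0.5, 15,  15),
        weak            = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3),
        quiescent1      = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05),
        quiescent2      = c(0.08, 0.05, 0.05, 0.05, 0.05, 0.05),
        quiescent3      = c(0.05, 0.08, 0.05, 0.05, 0.05, 0.05),
        quiescent4      = c(0.05, 0.05, 0.08, 0.05, 0.05, 0.05),
        quiescent5      = c(0.05, 0.05, 0.05, 0.08, 0.05, 0.05),
        quiescent6      = c(0.05, 0.05, 0.05, 0.05, 0.08, 0.05))
    colnames(m) <- .MARKS6
    m
}

#' Default planted expression groups
#'
#' Six planted profiles (log2 effects over the 8 design groups, in the order
#' siControl/siERG/siFLI1/siERG+siFLI1 at day 3, then day 7) emulating the
#' study's clusters: an EC-specific core cluster and a planted
#' direct-target (candidate) cluster, both driven by ERG/FLI1 and placed
#' next to EC-enhancer chromatin; an ERG-repressed cluster; two
#' synergistically derepressed clusters (up at day 3 vs day 7); and an
#' opposing-regulation group.  The `pattern` entries are the day-3
#' regulation-pattern labels each profile realizes under the package's
#' templates.
#'
#' @param nCandidates size of the planted candidate group (default 12).
#' @return list of group definitions.
#' @export
defaultClusterSpec <- function(nCandidates = 12L) {
    list(
        list(label = "ec_core", nGenes = 48L,
             effects = c(0, -1.2, -0.6, -1.6, 0, -2.2, -1.3, -2.8),
             noiseSd = 0.25, pattern = "VII", chromatin = "ec"),
        list(label = "ec_candidate", nGenes = as.integer(nCandidates),
             effects = c(0, -1.5, -1.0, -3.0, 0, -1.5, -1.0, -3.0),
             noiseSd = 0.25, pattern = "VII", chromatin = "ec_isolated"),
        list(label = "erg_repressed", nGenes = 40L,
             effects = c(0, 1.5, 0, 1.5, 0, 1.5, 0, 1.5),
             noiseSd = 0.25, pattern = "I", chromatin = "none"),
        list(label = "synergy_d3", nGenes = 30L,
             effects = c(0, 1.3, 0.4, 2.5, 0, 1.3, 0.4, 2.8),
             noiseSd = 0.25, pattern = "I", chromatin = "none"),
        list(label = "synergy_d7", nGenes = 30L,
             effects = c(0, 0.3, 0.1, 0.5, 0, 0.8, 0.4, 2.8),
             noiseSd = 0.25, pattern = "I", chromatin = "none"),
        list(label = "opposing", nGenes = 20L,
             effects = c(0, -1.5, 1.5, 0, 0, -1.5, 1.5, 0),
             noiseSd = 0.25, pattern = "VI", chromatin = "none"))
}

#' Build a simulation configuration
#'
#' @param seed master seed; the same configuration and seed give byte-
#'   identical outputs.
#' @param nChroms,chromLength genome shape (default 2 chromosomes of 1 Mb).
#' @param binSize bin width in bp (default 200).
#' @param emissionRates states x marks Poisson mean matrix (default
#'   [defaultEmissionRates()]).
#' @param stickiness stay-probability of the hidden chain; off-diagonal mass
#'   is uniform (default 0.98).
#' @param nGenes,nProbes genes and total probes (1-3 probes per gene).
#' @param nReplicates arrays per (treatment, day) group (default 2).
#' @param clusterSpec planted expression groups
#'   (default [defaultClusterSpec()]).
#' @param candidateSpec `list(nCandidates = <int>)`.
#' @param noiseScale global multiplier on all expression noise sds; 0 gives
#'   a noiseless matrix.
#' @param emissionFamily `"poisson"` (default) or `"nbinom"`.
#' @param nbSize negative-binomial size when `emissionFamily = "nbinom"`.
#' @param peakRateMin emission rate at or above which a state contributes to
#'   a mark's peak calls (default 5).
#' @param geneLengthRange gene length range in bp.
#' @param lowFlatFraction fraction of flat genes forced below the 300-signal
#'   filter in all groups.
#' @param baselineRange log2 baseline range for planted-cluster genes.
#' @param flatBaselineRange,lowFlatBaselineRange log2 baseline ranges for
#'   ordinary and forced-low flat genes.
#' @param affinityRange log2 probe-affinity range.
#' @param flatNoiseSd log2 noise sd for flat genes (scaled by `noiseScale`).
#' @return A validated [SimulationConfig-class].
#' @export
simulationConfig <- function(seed = 1L, nChroms = 2L, chromLength = 1e6,
                             binSize = 200L,
                             emissionRates = defaultEmissionRates(),
                             stickiness = 0.97, nGenes = 300L,
                             nProbes = 450L, nReplicates = 2L,
                             clusterSpec = NULL,
                             candidateSpec = list(nCandidates = 12L),
                             noiseScale = 1, emissionFamily = "poisson",
                             nbSize = 10, peakRateMin = 5,
                             geneLengthRange = c(1000L, 3000L),
                             lowFlatFraction = 0.5,
                             baselineRange = c(9.3, 10.5),
                             flatBaselineRange = c(8, 10),
                             lowFlatBaselineRange = c(5.5, 6.5),
                             affinityRange = c(-0.5, 0.5),
                             flatNoiseSd = 0.25) {
    if (is.null(clusterSpec))
        clusterSpec <- defaultClusterSpec(candidateSpec$nCandidates)
    new("SimulationConfig", seed = as.integer(seed),
        nChroms = as.integer(nChroms), chromLength = as.integer(chromLength),
        binSize = as.integer(binSize),
        nStatesTrue = nrow(emissionRates), emissionRates = emissionRates,
        stickiness = stickiness, nGenes = as.integer(nGenes),
        nProbes = as.integer(nProbes), nReplicates = as.integer(nReplicates),
        clusterSpec = clusterSpec, candidateSpec = candidateSpec,
        noiseScale = noiseScale, emissionFamily = emissionFamily,
        nbSize = nbSize, peakRateMin = peakRateMin,
        geneLengthRange = as.integer(geneLengthRange),
        lowFlatFraction = lowFlatFraction, baselineRange = baselineRange,
        flatBaselineRange = flatBaselineRange,
        lowFlatBaselineRange = lowFlatBaselineRange,
        affinityRange = affinityRange, flatNoiseSd = flatNoiseSd)
}

.chromNames <- function(config) paste0("chr", seq_len(config@nChroms))

.chromSizesOf <- function(config)
    setNames(rep(config@chromLength, config@nChroms), .chromNames(config))

## sample the hidden sticky-Markov state path for every chromosome
.sampleStatePaths <- function(config) {
    set.seed(config@seed + 202L)
    K <- config@nStatesTrue
    s <- config@stickiness
    nb <- as.integer(ceiling(config@chromLength / config@binSize))
    paths <- lapply(.chromNames(config), function(chrom) {
        p <- integer(nb)
        p[1] <- sample.int(K, 1L)
        stay <- runif(nb) < s
        for (t in 2:nb) {
            p[t] <- if (stay[t] || K == 1L) p[t - 1L]
                    else sample(setdiff(seq_len(K), p[t - 1L]), 1L)
        }
        p
    })
    names(paths) <- .chromNames(config)
    paths
}

## maximal runs of path positions whose state is in `states`
.stateRuns <- function(path, states) {
    r <- rle(path %in% states)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(startBin = starts[keep], endBin = ends[keep])
}

## states whose control H3K27Ac emits and is attenuated >= 2-fold after
## knockdown: the planted differential (EC-enhancer) states
.diffStates <- function(config) {
    er <- config@emissionRates
    which(er[, "H3K27Ac.siControl"] >= config@peakRateMin &
          er[, "H3K27Ac.siEF"] <= er[, "H3K27Ac.siControl"] / 2)
}

.k27cStates <- function(config)
    which(config@emissionRates[, "H3K27Ac.siControl"] >= config@peakRateMin)

#' Generate a gene annotation with uniformly placed genes
#'
#' Genes are placed uniformly at random, without overlap, with random
#' strand, on `nChroms` chromosomes of `chromLength` bp.  Deterministic
#' given the configuration seed.
#'
#' @param config a [SimulationConfig-class].
#' @return A [GenomeAnnotation-class].
#' @export
simulateGenome <- function(config) {
    set.seed(config@seed + 101L)
    sizes <- .chromSizesOf(config)
    occ <- lapply(sizes, function(x) list(s = numeric(0), e = numeric(0)))
    rows <- list()
    tries <- 0L
    maxTries <- 200L * config@nGenes
    while (length(rows) < config@nGenes) {
        if ((tries <- tries + 1L) > maxTries)
            stop("could not place ", config@nGenes, " non-overlapping ",
                 "genes; increase chromLength or reduce nGenes",
                 call. = FALSE)
        len <- sample(config@geneLengthRange[1]:config@geneLengthRange[2], 1L)
        chrom <- sample(names(sizes), 1L)
        s <- sample.int(sizes[[chrom]] - len, 1L)
        e <- s + len - 1L
        if (any(s <= occ[[chrom]]$e & e >= occ[[chrom]]$s)) next
        occ[[chrom]]$s <- c(occ[[chrom]]$s, s)
        occ[[chrom]]$e <- c(occ[[chrom]]$e, e)
        rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, start = s, end = e,
            strand = sample(c("+", "-"), 1L), stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    tab <- tab[order(match(tab$chrom, names(sizes)), tab$start), ]
    tab$gene_id <- sprintf("g%04d", seq_len(nrow(tab)))
    GenomeAnnotation(tab, sizes)
}

## Poisson (or NB) counts for all six mark columns given the state path
.emitCounts <- function(config, paths) {
    er <- config@emissionRates
    lapply(paths, function(p) {
        mu <- er[p, , drop = FALSE]
        cnt <- if (config@emissionFamily == "poisson")
            rpois(length(mu), mu)
        else rnbinom(length(mu), size = config@nbSize, mu = mu)
        matrix(cnt, nrow = length(p), ncol = ncol(er),
               dimnames = list(NULL, colnames(er)))
    })
}

## peak calls for one mark column: maximal runs of states emitting >= the
## peak rate floor; score = mean simulated count in the run, summit = offset
## of the maximum bin
.callPeaks <- function(config, paths, counts, markCol, target, condition) {
    states <- which(config@emissionRates[, markCol] >= config@peakRateMin)
    bs <- config@binSize
    grl <- lapply(names(paths), function(chrom) {
        runs <- .stateRuns(paths[[chrom]], states)
        if (!nrow(runs)) return(GRanges())
        v <- counts[[chrom]][, markCol]
        sc <- numeric(nrow(runs)); summit <- integer(nrow(runs))
        for (i in seq_len(nrow(runs))) {
            idx <- runs$startBin[i]:runs$endBin[i]
            sc[i] <- mean(v[idx])
            summit[i] <- (which.max(v[idx]) - 1L) * bs + bs %/% 2L
        }
        GRanges(chrom,
                IRanges((runs$startBin - 1L) * bs + 1L,
                        pmin(runs$endBin * bs, config@chromLength)),
                score = sc, summit_offset = summit)
    })
    gr <- suppressWarnings(do.call(c, grl))
    PeakSet(target, condition, gr)
}

#' Generate chromatin tracks, peak sets and state-path ground truth
#'
#' Samples the hidden state path (sticky Markov chain: stay-probability
#' `stickiness`, off-diagonal uniform), emits per-bin counts for the six
#' mark/condition tracks, derives ChIP peak sets as maximal runs of
#' emitting states, and records the planted differential-H3K27Ac regions
#' (EC-enhancer state runs, where the knockdown acetylation rate is
#' attenuated).
#'
#' @param config a [SimulationConfig-class].
#' @param annotation a [GenomeAnnotation-class] (chromosome sizes must match
#'   the configuration).
#' @param paths optional pre-sampled state paths (used by
#'   [simulateStudy()] so that gene placement can depend on the paths).
#' @return list with elements `control` and `knockdown`
#'   ([BinnedTrackSet-class]: ERG/FLI1/H3K4me3/H3K27Ac for the control
#'   condition, H3K4me3/H3K27Ac for the knockdown), `combined` (all six
#'   tracks, for segmentation), `peaks` (named list of [PeakSet-class]:
#'   `ERG`, `FLI1`, `H3K27Ac.siControl`, `H3K27Ac.siEF`) and `truth`.
#' @export
simulateChromatin <- function(config, annotation, paths = NULL) {
    if (is.null(paths)) paths <- .sampleStatePaths(config)
    set.seed(config@seed + 303L)
    counts <- .emitCounts(config, paths)
    bs <- config@binSize
    combined <- BinnedTrackSet(bs, counts, marks = .MARKS6)
    ctrlCols <- c("ERG", "FLI1", "H3K4me3.siControl", "H3K27Ac.siControl")
    kdCols <- c("H3K4me3.siEF", "H3K27Ac.siEF")
    control <- BinnedTrackSet(bs,
        lapply(counts, function(m) {
            x <- m[, ctrlCols, drop = FALSE]
            colnames(x) <- c("ERG", "FLI1", "H3K4me3", "H3K27Ac"); x
        }), marks = c("ERG", "FLI1", "H3K4me3", "H3K27Ac"))
    knockdown <- BinnedTrackSet(bs,
        lapply(counts, function(m) {
            x <- m[, kdCols, drop = FALSE]
            colnames(x) <- c("H3K4me3", "H3K27Ac"); x
        }), marks = c("H3K4me3", "H3K27Ac"))
    peaksOut <- list(
        ERG = .callPeaks(config, paths, counts, "ERG", "ERG", "siControl"),
        FLI1 = .callPeaks(config, paths, counts, "FLI1", "FLI1",
                          "siControl"),
        H3K27Ac.siControl = .callPeaks(config, paths, counts,
                                       "H3K27Ac.siControl", "H3K27Ac",
                                       "siControl"),
        H3K27Ac.siEF = .callPeaks(config, paths, counts, "H3K27Ac.siEF",
                                  "H3K27Ac", "siERG+siFLI1"))
    dStates <- .diffStates(config)
    diffTrue <- suppressWarnings(do.call(c, lapply(names(paths),
        function(chrom) {
            runs <- .stateRuns(paths[[chrom]], dStates)
            if (!nrow(runs)) return(GRanges())
            GRanges(chrom, IRanges((runs$startBin - 1L) * bs + 1L,
                                   pmin(runs$endBin * bs,
                                        config@chromLength)))
        })))
    list(control = control, knockdown = knockdown, combined = combined,
         peaks = peaksOut,
         truth = list(statePathTrue = paths,
                      differentialRegionsTrue = diffTrue,
                      ecStates = dStates))
}

## noiseless probe-level log2 design matrix (probe x 8 groups)
.probeDesign <- function(baseline, effects, affinity) {
    sweep(effects, 1L, baseline + affinity, `+`)
}

#' Generate the 8-group expression matrix with planted structure
#'
#' Genes are assigned to the planted groups of the cluster specification
#' (randomly, unless an explicit assignment is given); each gene's log2
#' baseline is drawn uniformly, the group's log2 effect vector is added per
#' design group, probes receive a log2 affinity offset and replicate-level
#' Gaussian noise, and values are exponentiated to the linear (MAS5-like)
#' scale.  Flat genes carry no effect; a configurable fraction of them is
#' forced below the 300-signal filter in all groups, and the remainder are
#' nearly constant so they fail the CV filter.
#'
#' @param config a [SimulationConfig-class].
#' @param annotation a [GenomeAnnotation-class].
#' @param groupAssignment optional named character vector gene_id -> group
#'   label (`"flat"` or a cluster-spec label).
#' @return list with `expression` (a [KnockdownExpression-class]) and
#'   `truth` (planted cluster/pattern/candidate labels and the probes that
#'   pass the signal/CV filters in the noiseless design).
#' @export
simulateExpression <- function(config, annotation, groupAssignment = NULL) {
    set.seed(config@seed + 404L)
    geneIds <- mcols(genes(annotation))$gene_id
    nG <- length(geneIds)
    spec <- config@clusterSpec
    if (is.null(groupAssignment)) {
        groupAssignment <- setNames(rep("flat", nG), geneIds)
        idx <- sample.int(nG)
        at <- 1L
        for (s in spec) {
            pick <- idx[at:(at + s$nGenes - 1L)]
            groupAssignment[pick] <- s$label
            at <- at + s$nGenes
        }
    }
    groupAssignment <- groupAssignment[geneIds]
    specByLabel <- setNames(spec, vapply(spec, `[[`, "", "label"))

    ## per-gene baseline and effects
    flat <- groupAssignment == "flat"
    nFlat <- sum(flat)
    lowFlat <- rep(FALSE, nG)
    if (nFlat > 0) {
        nLow <- round(config@lowFlatFraction * nFlat)
        lowFlat[which(flat)[sample.int(nFlat, nLow)]] <- TRUE
    }
    baseline <- numeric(nG)
    baseline[!flat] <- runif(sum(!flat), config@baselineRange[1],
                             config@baselineRange[2])
    baseline[flat & !lowFlat] <- runif(sum(flat & !lowFlat),
                                       config@flatBaselineRange[1],
                                       config@flatBaselineRange[2])
    baseline[lowFlat] <- runif(sum(lowFlat), config@lowFlatBaselineRange[1],
                               config@lowFlatBaselineRange[2])
    effects <- matrix(0, nG, 8L, dimnames = list(geneIds, .GROUPS))
    noiseSd <- rep(config@flatNoiseSd, nG)
    for (i in which(!flat)) {
        s <- specByLabel[[groupAssignment[i]]]
        effects[i, ] <- s$effects
        noiseSd[i] <- s$noiseSd
    }
    noiseSd <- noiseSd * config@noiseScale

    ## probe allocation: one per gene, extras at random (max 3 per gene)
    nExtra <- config@nProbes - nG
    probesPerGene <- rep(1L, nG)
    while (nExtra > 0L) {
        open <- which(probesPerGene < 3L)
        take <- sample(open, min(nExtra, length(open)))
        probesPerGene[take] <- probesPerGene[take] + 1L
        nExtra <- nExtra - length(take)
    }
    probeGene <- rep(seq_len(nG), probesPerGene)
    probeIds <- unlist(lapply(seq_len(nG), function(i)
        sprintf("%s_p%d", geneIds[i], seq_len(probesPerGene[i]))))
    affinity <- runif(length(probeIds), config@affinityRange[1],
                      config@affinityRange[2])

    ## noiseless probe x group design (log2)
    design <- effects[probeGene, , drop = FALSE] + baseline[probeGene] +
        affinity
    rownames(design) <- probeIds

    ## samples
    nr <- config@nReplicates
    sampleMeta <- data.frame(
        sample = sprintf("s%02d", seq_len(8L * nr)),
        treatment = rep(rep(.TREATMENTS, length.out = 8L), each = nr),
        day = rep(rep(.DAYS, each = 4L), each = nr),
        replicate = rep(seq_len(nr), times = 8L))
    vals <- matrix(0, length(probeIds), nrow(sampleMeta),
                   dimnames = list(probeIds, sampleMeta$sample))
    for (j in seq_len(nrow(sampleMeta))) {
        g <- .groupKey(sampleMeta$treatment[j], sampleMeta$day[j])
        vals[, j] <- 2^(design[, g] +
                        rnorm(length(probeIds), 0, noiseSd[probeGene]))
    }

    ## ground truth: noiseless filter evaluation (max group signal >= 300,
    ## CV over the 8 noiseless group means >= 0.5)
    lin <- 2^design
    cv <- apply(lin, 1L, sd) / rowMeans(lin)
    probesPassing <- probeIds[apply(lin, 1L, max) >= 300 & cv >= 0.5]

    patterns <- setNames(rep("other", nG), geneIds)
    for (s in spec)
        patterns[groupAssignment == s$label] <- s$pattern
    candLabel <- vapply(spec, function(s)
        identical(s$chromatin, "ec_isolated"), logical(1))
    candGroups <- vapply(spec, `[[`, "", "label")[candLabel]

    probeToGene <- setNames(geneIds[probeGene], probeIds)
    list(expression = KnockdownExpression(vals, probeToGene, sampleMeta),
         truth = list(
             clusterLabelsTrue = groupAssignment,
             patternLabelsTrue = patterns,
             candidatesTrue = geneIds[groupAssignment %in% candGroups],
             probesPassingTrue = probesPassing,
             baselineLog2 = setNames(baseline, geneIds),
             probeToGene = probeToGene))
}

## ladder of candidate TSS slots flanking a run (positions in bp);
## slots stay within `window` of the run so a gene placed there is
## guaranteed to have EC-enhancer bins near its TSS
.runSlots <- function(runStart, runEnd, chromLength, maxLen) {
    offs <- seq(1200L, 22550L, by = 3050L)
    down <- runEnd + offs                       # '+' gene: TSS = start
    up <- runStart - offs                       # '-' gene: TSS = end
    list(down = down[down + maxLen <= chromLength], up = up[up - maxLen >= 1])
}

#' Generate a complete synthetic study with linked ground truth
#'
#' Orchestrates the full generator: samples the hidden chromatin-state
#' paths first, then places the EC-cluster and candidate genes next to
#' planted EC-enhancer runs (candidates only next to "isolated" runs whose
#' neighbouring states carry no control H3K27Ac, so the enclosing
#' acetylation peak is exactly the attenuated region), places all remaining
#' genes away from EC-enhancer windows, and finally emits tracks, peaks and
#' the expression matrix.  By construction the planted candidate genes -
#' and only they - satisfy all five screening criteria in the noiseless
#' setting.
#'
#' @param config a [SimulationConfig-class].
#' @return list with `annotation`, `chromatin` (see [simulateChromatin()]),
#'   `expression` (a [KnockdownExpression-class]) and `truth` (merged
#'   ground-truth record; never consumed by the pipeline under test).
#' @export
simulateStudy <- function(config) {
    paths <- .sampleStatePaths(config)
    set.seed(config@seed + 1L)
    bs <- config@binSize
    sizes <- .chromSizesOf(config)
    dStates <- .diffStates(config)
    k27s <- .k27cStates(config)

    ## EC-enhancer runs.  A run is candidate-eligible ("isolated") when its
    ## neighbouring runs carry no control H3K27Ac (an acetylated neighbour
    ## would merge into, and dilute, the differential acetylation peak) and
    ## the run spans >= 3 bins, which gives the differential binomial test
    ## overwhelming power at the planted 4-fold attenuation.  The midpoints
    ## of the merged ERG and FLI1 peak runs containing the EC run are also
    ## recorded: a candidate TSS must fall within the screen window of both.
    er <- config@emissionRates
    ergStates <- which(er[, "ERG"] >= config@peakRateMin)
    fliStates <- which(er[, "FLI1"] >= config@peakRateMin)
    excl <- setdiff(k27s, dStates)
    spanMid <- function(p, a, b, states) {
        while (a > 1L && p[a - 1L] %in% states) a <- a - 1L
        while (b < length(p) && p[b + 1L] %in% states) b <- b + 1L
        as.integer(((a - 1L) * bs + 1L + b * bs) %/% 2L)
    }
    runTab <- do.call(rbind, lapply(names(paths), function(chrom) {
        p <- paths[[chrom]]
        runs <- .stateRuns(p, dStates)
        if (!nrow(runs)) return(NULL)
        isolated <- vapply(seq_len(nrow(runs)), function(i) {
            lhs <- runs$startBin[i] - 1L
            rhs <- runs$endBin[i] + 1L
            (runs$endBin[i] - runs$startBin[i] + 1L >= 3L) &&
            (lhs < 1L || !(p[lhs] %in% excl)) &&
            (rhs > length(p) || !(p[rhs] %in% excl))
        }, logical(1))
        data.frame(chrom = chrom,
                   start = (runs$startBin - 1L) * bs + 1L,
                   end = pmin(runs$endBin * bs, sizes[[chrom]]),
                   isolated = isolated,
                   ergMid = vapply(seq_len(nrow(runs)), function(i)
                       spanMid(p, runs$startBin[i], runs$endBin[i],
                               ergStates), integer(1)),
                   fliMid = vapply(seq_len(nrow(runs)), function(i)
                       spanMid(p, runs$startBin[i], runs$endBin[i],
                               fliStates), integer(1)),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(runTab) || !nrow(runTab))
        stop("no EC-enhancer runs sampled; increase chromLength or adjust ",
             "emission rates", call. = FALSE)

    maxLen <- config@geneLengthRange[2]
    slotTab <- do.call(rbind, lapply(seq_len(nrow(runTab)), function(i) {
        sl <- .runSlots(runTab$start[i], runTab$end[i],
                        sizes[[runTab$chrom[i]]], maxLen)
        rbind(
            if (length(sl$down))
                data.frame(chrom = runTab$chrom[i], pos = sl$down,
                           side = "down", isolated = runTab$isolated[i],
                           ergMid = runTab$ergMid[i],
                           fliMid = runTab$fliMid[i],
                           rank = seq_along(sl$down)),
            if (length(sl$up))
                data.frame(chrom = runTab$chrom[i], pos = sl$up,
                           side = "up", isolated = runTab$isolated[i],
                           ergMid = runTab$ergMid[i],
                           fliMid = runTab$fliMid[i],
                           rank = seq_along(sl$up)))
    }))
    ## fill close-in slots across all runs first (spreads genes over runs)
    slotTab <- slotTab[order(slotTab$rank, slotTab$chrom, slotTab$pos), ]

    spec <- config@clusterSpec
    labels <- vapply(spec, `[[`, "", "label")
    wantEC <- unlist(lapply(spec, function(s)
        if (s$chromatin %in% c("ec", "ec_isolated"))
            rep(s$label, s$nGenes) else character(0)))
    ## candidates first (they need isolated runs)
    wantEC <- wantEC[order(wantEC != "ec_candidate")]

    occ <- lapply(sizes, function(x) list(s = numeric(0), e = numeric(0)))
    addOcc <- function(chrom, s, e) {
        occ[[chrom]]$s <<- c(occ[[chrom]]$s, s)
        occ[[chrom]]$e <<- c(occ[[chrom]]$e, e)
    }
    clash <- function(chrom, s, e)
        any(s <= occ[[chrom]]$e & e >= occ[[chrom]]$s)

    geneRows <- list()
    lens <- sample(config@geneLengthRange[1]:config@geneLengthRange[2],
                   length(wantEC) + config@nGenes, replace = TRUE)
    li <- 0L
    usedSlots <- rep(FALSE, nrow(slotTab))
    for (lab in wantEC) {
        li <- li + 1L
        len <- lens[li]
        needIso <- identical(
            spec[[match(lab, labels)]]$chromatin, "ec_isolated")
        ok <- FALSE
        for (si in seq_len(nrow(slotTab))) {
            if (usedSlots[si]) next
            if (needIso && !slotTab$isolated[si]) next
            ## candidate TSS must also sit within the screen window of both
            ## merged TF peak midpoints
            if (needIso &&
                (abs(slotTab$pos[si] - slotTab$ergMid[si]) > 24000 ||
                 abs(slotTab$pos[si] - slotTab$fliMid[si]) > 24000)) next
            if (slotTab$side[si] == "down") {
                s <- slotTab$pos[si]; e <- s + len - 1L; strandC <- "+"
            } else {
                e <- slotTab$pos[si]; s <- e - len + 1L; strandC <- "-"
            }
            chrom <- slotTab$chrom[si]
            if (clash(chrom, s, e)) next
            usedSlots[si] <- TRUE
            addOcc(chrom, s, e)
            geneRows[[length(geneRows) + 1L]] <-
                list(label = lab, chrom = chrom, start = s, end = e,
                     strand = strandC)
            ok <- TRUE
            break
        }
        if (!ok)
            stop("not enough EC-enhancer-adjacent slots to place planted ",
                 "gene group '", lab, "'; increase chromLength",
                 call. = FALSE)
    }

    ## all other genes: uniform, TSS kept > 25 kb from any EC-enhancer bin
    avoid <- lapply(names(sizes), function(chrom) {
        i <- runTab$chrom == chrom
        list(s = pmax(1, runTab$start[i] - 25000),
             e = pmin(sizes[[chrom]], runTab$end[i] + 25000))
    })
    names(avoid) <- names(sizes)
    nOther <- config@nGenes - length(wantEC)
    nOtherPlanted <- sum(vapply(spec, function(s)
        if (!s$chromatin %in% c("ec", "ec_isolated")) s$nGenes else 0L,
        integer(1)))
    if (nOther < nOtherPlanted)
        stop("nGenes too small for the cluster specification", call. = FALSE)
    otherLabels <- c(unlist(lapply(spec, function(s)
        if (!s$chromatin %in% c("ec", "ec_isolated"))
            rep(s$label, s$nGenes) else character(0))),
        rep("flat", nOther - nOtherPlanted))
    tries <- 0L
    for (lab in otherLabels) {
        li <- li + 1L
        len <- lens[li]
        repeat {
            if ((tries <- tries + 1L) > 500L * config@nGenes)
                stop("could not place genes away from EC-enhancer runs; ",
                     "increase chromLength", call. = FALSE)
            chrom <- sample(names(sizes), 1L)
            s <- sample.int(sizes[[chrom]] - len, 1L)
            e <- s + len - 1L
            strandC <- sample(c("+", "-"), 1L)
            tpos <- if (strandC == "+") s else e
            if (clash(chrom, s, e)) next
            if (any(tpos >= avoid[[chrom]]$s & tpos <= avoid[[chrom]]$e))
                next
            addOcc(chrom, s, e)
            geneRows[[length(geneRows) + 1L]] <-
                list(label = lab, chrom = chrom, start = s, end = e,
                     strand = strandC)
            break
        }
    }

    tab <- do.call(rbind, lapply(geneRows, function(r)
        data.frame(label = r$label, chrom = r$chrom, start = r$start,
                   end = r$end, strand = r$strand,
                   stringsAsFactors = FALSE)))
    ord <- order(match(tab$chrom, names(sizes)), tab$start)
    tab <- tab[ord, ]
    tab$gene_id <- sprintf("g%04d", seq_len(nrow(tab)))
    groupAssignment <- setNames(tab$label, tab$gene_id)
    annotation <- GenomeAnnotation(tab, sizes)

    chromatin <- simulateChromatin(config, annotation, paths = paths)
    expr <- simulateExpression(config, annotation, groupAssignment)

    truth <- c(chromatin$truth, expr$truth,
               list(geneGroups = groupAssignment))
    list(annotation = annotation, chromatin = chromatin,
         expression = expr$expression, truth = truth)
}

#' Write a simulated study to disk
#'
#' Writes the annotation (TSV + chrom.sizes), one bedGraph per mark/
#' condition track, one narrowPeak file per peak set, the expression matrix
#' and sample metadata TSVs, and `ground_truth.json`.
#'
#' @param sim result of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(...) file.path(dir, ...)
    writeGeneAnnotation(sim$annotation, fp("genes.tsv"), fp("chrom.sizes"))
    comb <- sim$chromatin$combined
    for (m in marks(comb))
        writeBedGraph(comb, m, fp(paste0(m, ".bedGraph")))
    for (nm in names(sim$chromatin$peaks))
        writePeaks(sim$chromatin$peaks[[nm]],
                   fp(paste0(nm, ".narrowPeak")), format = "narrowPeak")
    writeExpression(sim$expression, fp("expression.tsv"),
                    fp("sample_meta.tsv"))
    truth <- sim$truth
    diffGr <- truth$differentialRegionsTrue
    truthJson <- list(
        statePathTrue = truth$statePathTrue,
        differentialRegionsTrue = data.frame(
            chrom = as.character(seqnames(diffGr)),
            start = start(diffGr), end = end(diffGr)),
        ecStates = truth$ecStates,
        clusterLabelsTrue = as.list(truth$clusterLabelsTrue),
        patternLabelsTrue = as.list(truth$patternLabelsTrue),
        candidatesTrue = truth$candidatesTrue,
        probesPassingTrue = truth$probesPassingTrue,
        geneGroups = as.list(truth$geneGroups))
    write_json(truthJson, fp("ground_truth.json"), auto_unbox = TRUE,
               digits = NA)
    invisible(dir)
}
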