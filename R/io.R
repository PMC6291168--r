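## Readers/writers for BED/narrowPeak, bedGraph, gene annotation and
## expression tables.  External files use the BED dialect (0-based,
## half-open, tab-separated, LF); internal objects are GRanges (1-based,
## closed).  Conversion happens here and only here.

.readLinesStrict <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path)
    lines[nzchar(lines) & !startsWith(lines, "#") &
          !startsWith(lines, "track")]
}

.splitFields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read a BED or narrowPeak file into a PeakSet
#'
#' BED input requires >= 3 columns (chrom, start, end; optional name, score).
#' narrowPeak (ENCODE 10-column) maps column 7 (signalValue) to `score` and
#' column 10 to `summit_offset` (`-1` becomes `NA`).  Coordinates are 0-based
#' half-open on disk and converted to 1-based closed `GRanges`.
#'
#' @param path input file.
#' @param format `"bed"` or `"narrowPeak"`.
#' @param target,condition labels stored on the returned [PeakSet-class].
#' @return A `PeakSet` sorted by (chrom, start).
#' @export
readPeaks <- function(path, format = c("bed", "narrowPeak"),
                      target = "peak", condition = "siControl") {
    format <- match.arg(format)
    lines <- .readLinesStrict(path)
    if (!length(lines))
        return(PeakSet(target, condition, GRanges()))
    fields <- .splitFields(lines)
    need <- if (format == "bed") 3L else 10L
    nf <- lengths(fields)
    if (any(nf < need))
        stop(sprintf("malformed %s line %d: expected >= %d fields, got %d",
                     format, which(nf < need)[1], need, min(nf[nf < need])),
             call. = FALSE)
    chrom <- vapply(fields, `[[`, "", 1L)
    start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
    end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
    bad <- which(!is.finite(start0) | !is.finite(end0))
    if (length(bad))
        stop("non-numeric coordinates at line ", bad[1], call. = FALSE)
    ge <- which(start0 >= end0)
    if (length(ge))
        stop("start >= end at line ", ge[1], call. = FALSE)
    if (format == "narrowPeak") {
        sc <- as.numeric(vapply(fields, `[[`, "", 7L))
        summit <- as.integer(vapply(fields, `[[`, "", 10L))
        summit[summit < 0L] <- NA_integer_
    } else {
        sc <- ifelse(nf >= 5L,
                     suppressWarnings(as.numeric(
                         vapply(fields, function(f)
                             if (length(f) >= 5L) f[[5L]] else "0", ""))),
                     0)
        sc[!is.finite(sc)] <- 0
        summit <- rep(NA_integer_, length(lines))
    }
    gr <- GRanges(chrom, IRanges(start0 + 1L, end0),
                  score = sc, summit_offset = summit)
    PeakSet(target, condition, gr)
}

#' Write a PeakSet
#'
#' Writes BED5 (chrom, start, end, name, score) or 10-column narrowPeak with
#' 0-based half-open coordinates.  Scores are written at full precision
#' (`%.17g`) so that `readPeaks(writePeaks(x))` round-trips coordinates and
#' scores bit-exactly.
#'
#' @param x a [PeakSet-class].
#' @param path output file.
#' @param format `"bed"` or `"narrowPeak"`.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(x, path, format = c("bed", "narrowPeak")) {
    format <- match.arg(format)
    gr <- peaks(x)
    nm <- sprintf("%s_%d", peakTarget(x), seq_along(gr))
    sc <- sprintf("%.17g", mcols(gr)$score)
    if (format == "bed") {
        lines <- paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                       nm, sc, sep = "\t")
    } else {
        summit <- mcols(gr)$summit_offset
        summit[is.na(summit)] <- -1L
        lines <- paste(as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                       nm, 0L, ".", sc, -1L, -1L, summit, sep = "\t")
    }
    writeLines(lines, path)
    invisible(path)
}

#' Read a gene annotation table
#'
#' Expects a tab-separated table with header columns `gene_id`, `chrom`,
#' `start`, `end`, `strand` (0-based half-open, BED-like) plus a two-column
#' chrom.sizes file (`chrom`, `length`).
#'
#' @param path gene table path.
#' @param chromSizesPath chrom.sizes path.
#' @return A [GenomeAnnotation-class].
#' @export
readGeneAnnotation <- function(path, chromSizesPath) {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    cs <- read.table(chromSizesPath, header = FALSE, sep = "\t",
                     stringsAsFactors = FALSE)
    sizes <- setNames(as.integer(cs[[2]]), cs[[1]])
    GenomeAnnotation(data.frame(gene_id = tab$gene_id, chrom = tab$chrom,
                                start = tab$start + 1L, end = tab$end,
                                strand = tab$strand),
                     chromSizes = sizes)
}

#' Write a gene annotation table (plus chrom.sizes)
#'
#' @param x a [GenomeAnnotation-class].
#' @param path gene table output path (0-based half-open coordinates).
#' @param chromSizesPath chrom.sizes output path.
#' @return `path`, invisibly.
#' @export
writeGeneAnnotation <- function(x, path, chromSizesPath) {
    gr <- genes(x)
    tab <- data.frame(gene_id = mcols(gr)$gene_id,
                      chrom = as.character(seqnames(gr)),
                      start = start(gr) - 1L, end = end(gr),
                      strand = as.character(strand(gr)))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    sizes <- chromSizes(x)
    writeLines(paste(names(sizes), sizes, sep = "\t"), chromSizesPath)
    invisible(path)
}

#' Read bedGraph coverage into genome-tiling bins
#'
#' Each mark's bedGraph is resampled onto non-overlapping `binSize`-bp bins
#' tiling every chromosome of the annotation.  A record's value is treated
#' as signal density per `binSize` bp: a bin receives `value * overlap /
#' binSize`, so intervals straddling bin boundaries are prorated by overlap
#' fraction and total mass `sum(value * length) / binSize` is conserved.
#' Bins and whole chromosomes without records are zero-filled (the latter
#' with a warning, since ChIP inputs often omit empty chromosomes).
#'
#' @param paths named character vector, mark name -> bedGraph path.
#' @param annotation a [GenomeAnnotation-class] providing chromosome sizes.
#' @param binSize bin width in bp (default 200).
#' @return A [BinnedTrackSet-class].
#' @export
readBinnedTracks <- function(paths, annotation, binSize = 200L) {
    sizes <- chromSizes(annotation)
    nb <- setNames(as.integer(ceiling(sizes / binSize)), names(sizes))
    counts <- lapply(nb, function(n)
        matrix(0, nrow = n, ncol = length(paths),
               dimnames = list(NULL, names(paths))))
    for (j in seq_along(paths)) {
        lines <- .readLinesStrict(paths[[j]])
        if (!length(lines)) next
        fields <- .splitFields(lines)
        if (any(lengths(fields) < 4L))
            stop("malformed bedGraph line ",
                 which(lengths(fields) < 4L)[1], call. = FALSE)
        chrom <- vapply(fields, `[[`, "", 1L)
        s0 <- as.numeric(vapply(fields, `[[`, "", 2L))
        e0 <- as.numeric(vapply(fields, `[[`, "", 3L))
        val <- as.numeric(vapply(fields, `[[`, "", 4L))
        if (any(!chrom %in% names(sizes)))
            stop("bedGraph chromosome absent from annotation: ",
                 chrom[!chrom %in% names(sizes)][1], call. = FALSE)
        if (any(val < 0))
            stop("negative bedGraph value at line ", which(val < 0)[1],
                 call. = FALSE)
        for (i in seq_along(chrom)) {
            b0 <- floor(s0[i] / binSize)
            b1 <- ceiling(e0[i] / binSize) - 1
            for (b in b0:b1) {
                lo <- max(s0[i], b * binSize)
                hi <- min(e0[i], (b + 1) * binSize)
                counts[[chrom[i]]][b + 1L, j] <-
                    counts[[chrom[i]]][b + 1L, j] + val[i] * (hi - lo) / binSize
            }
        }
        missing <- setdiff(names(sizes), unique(chrom))
        if (length(missing))
            warning(sprintf("mark '%s': no records for %s; zero-filled",
                            names(paths)[j],
                            paste(missing, collapse = ", ")),
                    call. = FALSE)
    }
    BinnedTrackSet(binSize, counts, marks = names(paths))
}

#' Write one mark of a BinnedTrackSet as bedGraph
#'
#' Zero bins are omitted; runs of equal value are not merged (one record per
#' non-zero bin), which keeps the writer trivially invertible.
#'
#' @param x a [BinnedTrackSet-class].
#' @param mark mark name to export.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedGraph <- function(x, mark, path) {
    stopifnot(mark %in% marks(x))
    bs <- binSize(x)
    con <- file(path, "w")
    on.exit(close(con))
    for (chrom in names(trackCounts(x))) {
        v <- trackCounts(x)[[chrom]][, mark]
        nz <- which(v != 0)
        if (length(nz))
            writeLines(paste(chrom, (nz - 1L) * bs, nz * bs,
                             sprintf("%.17g", v[nz]), sep = "\t"), con)
    }
    invisible(path)
}

#' Read an expression matrix and its sample metadata
#'
#' The matrix is tab-separated with a header of sample ids and first column
#' `probe_id` (an optional second column `gene_id` is used when present; a
#' separate probe-to-gene map can be passed instead).  The metadata table
#' maps sample id to `treatment`, `day` and `replicate`; treatments are
#' restricted to siControl, siERG, siFLI1 and siERG+siFLI1.
#'
#' @param path expression matrix path.
#' @param metaPath sample metadata path.
#' @param probeToGene optional named character vector probe -> gene,
#'   overriding any `gene_id` column.
#' @return A [KnockdownExpression-class].
#' @export
readExpression <- function(path, metaPath, probeToGene = NULL) {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE, colClasses = "character")
    if (anyDuplicated(tab[[1]]))
        stop("duplicate probe_id: ", tab[[1]][duplicated(tab[[1]])][1],
             call. = FALSE)
    hasGene <- identical(colnames(tab)[2], "gene_id")
    first <- if (hasGene) 3L else 2L
    vals <- as.matrix(tab[, first:ncol(tab), drop = FALSE])
    num <- suppressWarnings(apply(vals, 2L, as.numeric))
    if (any(is.na(num))) {
        idx <- which(is.na(num), arr.ind = TRUE)[1, ]
        stop(sprintf("non-numeric value for probe '%s' in sample '%s'",
                     tab[[1]][idx[1]], colnames(vals)[idx[2]]),
             call. = FALSE)
    }
    rownames(num) <- tab[[1]]
    meta <- read.table(metaPath, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
    if (any(!meta$treatment %in% .TREATMENTS))
        stop("unknown treatment '",
             meta$treatment[!meta$treatment %in% .TREATMENTS][1],
             "'; allowed: ", paste(.TREATMENTS, collapse = ", "),
             call. = FALSE)
    if (any(!meta$sample %in% colnames(num)))
        stop("sample in metadata but not in matrix: ",
             meta$sample[!meta$sample %in% colnames(num)][1], call. = FALSE)
    num <- num[, meta$sample, drop = FALSE]
    if (is.null(probeToGene)) {
        if (hasGene) probeToGene <- setNames(tab$gene_id, tab[[1]])
        else probeToGene <- setNames(rownames(num), rownames(num))
    }
    KnockdownExpression(num, probeToGene, meta)
}

#' Write an expression matrix and sample metadata
#'
#' @param x a [KnockdownExpression-class].
#' @param path matrix output path.
#' @param metaPath metadata output path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path, metaPath) {
    vals <- assay(x, "signal")
    tab <- data.frame(probe_id = rownames(vals),
                      gene_id = rowData(x)$gene_id,
                      apply(vals, 2L, function(v) sprintf("%.17g", v)),
                      check.names = FALSE)
    colnames(tab)[-(1:2)] <- colnames(vals)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    cd <- colData(x)
    meta <- data.frame(sample = rownames(cd),
                       treatment = as.character(cd$treatment),
                       day = as.character(cd$day),
                       replicate = cd$replicate)
    write.table(meta, metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
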