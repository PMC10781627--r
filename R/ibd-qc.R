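#' Filter IBD segments on LOD score and genetic length
#'
#' A segment is kept iff \code{lod >= min_lod} AND
#' \code{length_cm >= min_cm}; both comparisons are inclusive, following
#' the printed operators of the filtering rule. Input order is preserved.
#' The default thresholds (LOD >= 3, length >= 2 cM) are the main-analysis
#' setting; ROH analyses and fine-scale clustering use a more lenient 1 cM
#' minimum (\code{mode}).
#'
#' @param x an \code{IBDSegments} object.
#' @param min_lod minimum LOD score (inclusive), default 3.
#' @param min_cm minimum genetic length in cM (inclusive); default set by
#'   \code{mode}.
#' @param mode one of \code{"analysis"} (2 cM), \code{"clustering"} (1 cM),
#'   \code{"roh"} (1 cM); ignored when \code{min_cm} is given.
#' @return the filtered \code{IBDSegments}.
#' @export
filterSegments <- function(x, min_lod = 3, min_cm = NULL,
                           mode = c("analysis", "clustering", "roh")) {
    mode <- match.arg(mode)
    if (is.null(min_cm)) min_cm <- c(analysis = 2, clustering = 1, roh = 1)[[mode]]
    if (min_lod < 0 || min_cm < 0) stop("thresholds must be non-negative")
    s <- segmentTable(x)
    keep <- s$lod >= min_lod & s$length_cm >= min_cm
    x[keep]
}

# bp-length-weighted trimmed mean and s.d. of a coverage profile.
# trim is the fraction of total bp mass removed from EACH tail; partial
# intervals at the trim boundary contribute their remaining mass.
.weightedTrimmedStats <- function(values, weights, trim) {
    o <- order(values)
    v <- values[o]; w <- as.numeric(weights[o])
    W <- sum(w)
    lo <- trim * W; hi <- (1 - trim) * W
    cw <- cumsum(w)
    prev <- c(0, cw[-length(cw)])
    # mass of each interval inside [lo, hi]
    m <- pmax(0, pmin(cw, hi) - pmax(prev, lo))
    M <- sum(m)
    if (M <= 0) stop("trim fraction removes all mass")
    mu <- sum(m * v) / M
    sdv <- sqrt(sum(m * (v - mu)^2) / M)
    c(mean = mu, sd = sdv)
}

#' Per-position pileup of long IBD segments
#'
#' Counts, at every position of every chromosome in the map, the number of
#' long IBD segments (genetic length strictly greater than \code{long_cm})
#' overlapping that position. Computed exactly as run-length-encoded
#' coverage; breakpoints are the union of qualifying segment endpoints.
#'
#' @param x QC-filtered \code{IBDSegments}.
#' @param map a \code{GenomeMap} (defines chromosome extents).
#' @param long_cm length threshold in cM, strict; default 10.
#' @return a \code{\link[=PileupProfile-class]{PileupProfile}}.
#' @importFrom GenomicRanges coverage
#' @export
computePileup <- function(x, map, long_cm = 10) {
    s <- segmentTable(x)
    unknown <- setdiff(unique(s$chrom), chromosomes(map))
    if (length(unknown))
        stop("segment chromosome(s) absent from map: ",
             paste(unknown, collapse = ", "))
    long <- s[s$length_cm > long_cm, , drop = FALSE]
    lens <- chromLengthsBp(map)
    gr <- GenomicRanges::GRanges(
        seqnames = factor(long$chrom, levels = names(lens)),
        ranges = IRanges::IRanges(start = long$start_bp + 1,
                                  end = long$end_bp),
        seqlengths = lens)
    cov <- GenomicRanges::coverage(gr)
    new("PileupProfile", cov = cov, long_cm = long_cm)
}

setMethod("show", "PileupProfile", function(object) {
    mx <- suppressWarnings(max(vapply(object@cov, max, 0)))
    cat(sprintf("PileupProfile: %d chromosome(s), long_cm > %g, max count %d\n",
                length(object@cov), object@long_cm, as.integer(mx)))
})

#' Detect regions of excess long IBD
#'
#' Computes the bp-length-weighted trimmed mean m and trimmed s.d. s of the
#' per-position long-segment counts over all chromosomes (3\% of mass
#' trimmed from each tail by default) and flags every maximal run of
#' positions with count strictly greater than m + z*s, merging adjacent
#' flagged intervals. Excess is one-sided: regions of unusually low IBD are
#' never flagged.
#'
#' @param pileup a \code{PileupProfile}.
#' @param trim_fraction mass fraction trimmed from each tail, default 0.03.
#' @param z number of trimmed standard deviations above the trimmed mean,
#'   default 10.
#' @return a \code{GRanges} of excess regions (0-based starts in
#'   \code{mcols()$start_bp}/\code{end_bp}) with peak count and the
#'   threshold used; empty when nothing exceeds the threshold.
#' @importFrom IRanges slice
#' @export
detectExcessRegions <- function(pileup, trim_fraction = 0.03, z = 10) {
    cov <- pileup@cov
    if (length(cov) == 0L) stop("empty pileup")
    vals <- unlist(lapply(cov, S4Vectors::runValue), use.names = FALSE)
    wids <- unlist(lapply(cov, S4Vectors::runLength), use.names = FALSE)
    st <- .weightedTrimmedStats(vals, wids, trim_fraction)
    thr <- st[["mean"]] + z * st[["sd"]]
    out <- list()
    for (ch in names(cov)) {
        sl <- IRanges::slice(cov[[ch]], lower = thr, includeLower = FALSE)
        if (length(sl) == 0L) next
        rng <- IRanges::ranges(sl)
        out[[ch]] <- data.frame(chrom = ch, start = IRanges::start(rng),
                                end = IRanges::end(rng))
    }
    if (length(out) == 0L) {
        res <- GenomicRanges::GRanges()
        S4Vectors::mcols(res) <- S4Vectors::DataFrame(
            peak_count = numeric(0), threshold = numeric(0))
        return(res)
    }
    rd <- do.call(rbind, out)
    res <- GenomicRanges::GRanges(
        seqnames = rd$chrom,
        ranges = IRanges::IRanges(start = rd$start, end = rd$end))
    res <- GenomicRanges::reduce(res, min.gapwidth = 1L,
                                 with.revmap = FALSE, ignore.strand = TRUE)
    # reduce drops mcols; recompute peaks per merged region
    pk <- vapply(seq_along(res), function(i) {
        ch <- as.character(GenomicRanges::seqnames(res))[i]
        IRanges::viewMaxs(IRanges::Views(cov[[ch]],
                                         IRanges::ranges(res[i])))
    }, 0)
    S4Vectors::mcols(res)$peak_count <- pk
    S4Vectors::mcols(res)$threshold <- thr
    res
}

#' Remove segments overlapping excess-IBD regions
#'
#' A segment is dropped iff it overlaps any excess region by at least one
#' base (any overlap, not containment). Abutting under the half-open
#' convention does not count as overlap. The number removed is logged.
#'
#' @param x an \code{IBDSegments} object.
#' @param regions \code{GRanges} from \code{\link{detectExcessRegions}}.
#' @return the surviving \code{IBDSegments}.
#' @importFrom GenomicRanges findOverlaps
#' @export
removeExcess <- function(x, regions) {
    if (length(regions) == 0L || length(x) == 0L) return(x)
    gr <- as(x, "GRanges")
    hits <- GenomicRanges::findOverlaps(gr, regions, ignore.strand = TRUE)
    drop <- unique(S4Vectors::queryHits(hits))
    message(length(drop), " of ", length(x),
            " segments overlap excess-IBD regions; removed")
    if (length(drop)) x[-drop] else x
}

#' Pairwise genome-fraction sharing matrix
#'
#' Entry (i, j) is the summed cM length of IBD segments between i and j,
#' after taking the union of overlapping same-pair segments per chromosome
#' (so haplotype-level duplicates are not double-counted), divided by the
#' total genetic map length; clipped to at most 1. HBD rows are excluded.
#'
#' @param x QC-filtered \code{IBDSegments}.
#' @param map a \code{GenomeMap}.
#' @param samples character vector of sample IDs fixing matrix order; every
#'   sample occurring in \code{x} must be listed.
#' @return a \code{\link[=SharingMatrix-class]{SharingMatrix}}.
#' @export
sharingMatrix <- function(x, map, samples) {
    s <- segmentTable(x)
    s <- s[!s$hbd, , drop = FALSE]
    miss <- setdiff(unique(c(s$sample_a, s$sample_b)), samples)
    if (length(miss))
        stop("segment sample(s) absent from sample list: ",
             paste(miss, collapse = ", "))
    m <- matrix(0, length(samples), length(samples),
                dimnames = list(samples, samples))
    if (nrow(s)) {
        pair <- paste(s$sample_a, s$sample_b, sep = "\r")
        key <- paste(pair, s$chrom, sep = "\r")
        gr <- GenomicRanges::GRanges(
            seqnames = key,
            ranges = IRanges::IRanges(start = s$start_bp + 1, end = s$end_bp))
        red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
        parts <- strsplit(as.character(GenomicRanges::seqnames(red)), "\r",
                          fixed = TRUE)
        a <- vapply(parts, `[`, "", 1L)
        b <- vapply(parts, `[`, "", 2L)
        ch <- vapply(parts, `[`, "", 3L)
        cm <- .intervalCm(map, ch, GenomicRanges::start(red) - 1,
                          GenomicRanges::end(red))
        tot <- rowsum(cm, paste(a, b, sep = "\r"))
        pr <- strsplit(rownames(tot), "\r", fixed = TRUE)
        for (k in seq_along(pr)) {
            i <- pr[[k]][1]; j <- pr[[k]][2]
            v <- min(tot[k, 1] / totalCm(map), 1)
            m[i, j] <- v; m[j, i] <- v
        }
    }
    diag(m) <- 0
    new("SharingMatrix", mat = m)
}

#' @rdname SharingMatrix-class
#' @export
setMethod("sharingValues", "SharingMatrix", function(x) x@mat)

setMethod("show", "SharingMatrix", function(object) {
    m <- object@mat
    ut <- m[upper.tri(m)]
    cat(sprintf("SharingMatrix: %d samples, %d nonzero pairs, max %.4g\n",
                nrow(m), sum(ut > 0), if (length(ut)) max(ut) else 0))
})
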