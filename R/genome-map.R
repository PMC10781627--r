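#' Load a genome map from a TSV anchor file
#'
#' Reads a tab-delimited file with header \code{chrom pos_bp pos_cm}
#' (comment lines starting with \code{#} are ignored). Each chromosome
#' needs at least two anchor points; a chromosome given as a single row is
#' interpreted as its terminal anchor with an implicit (0 bp, 0 cM) origin,
#' so a one-row-per-chromosome file of chromosome lengths is also accepted.
#'
#' @param path path to the map file.
#' @return a validated \code{\link[=GenomeMap-class]{GenomeMap}}.
#' @examples
#' f <- tempfile()
#' writeLines(c("chrom\tpos_bp\tpos_cm", "chr1\t100000000\t100"), f)
#' m <- loadGenomeMap(f)
#' totalCm(m)
#' @export
loadGenomeMap <- function(path) {
    a <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
    names(a) <- sub("^pos_", "", names(a))
    if (!all(c("chrom", "bp", "cm") %in% names(a)))
        stop("map file must have columns chrom, pos_bp, pos_cm")
    a$chrom <- as.character(a$chrom)
    parts <- lapply(split(a, a$chrom), function(x) {
        x <- x[order(x$bp), , drop = FALSE]
        if (nrow(x) == 1L && x$bp > 0)
            x <- rbind(data.frame(chrom = x$chrom, bp = 0, cm = 0), x)
        x
    })
    anchors <- do.call(rbind, parts[unique(a$chrom)])
    rownames(anchors) <- NULL
    new("GenomeMap", anchors = anchors[, c("chrom", "bp", "cm")])
}

#' Construct a uniform genome map in code
#'
#' Convenience constructor for maps with a constant recombination rate per
#' chromosome: each chromosome gets two anchors, (0, 0) and
#' (\code{length_bp}, \code{length_cm}).
#'
#' @param chrom chromosome identifiers.
#' @param length_bp physical lengths in bp.
#' @param length_cm genetic lengths in cM.
#' @return a \code{GenomeMap}.
#' @export
uniformGenomeMap <- function(chrom, length_bp, length_cm) {
    anchors <- data.frame(
        chrom = rep(as.character(chrom), each = 2L),
        bp = as.numeric(rbind(0, length_bp)),
        cm = as.numeric(rbind(0, length_cm)))
    new("GenomeMap", anchors = anchors)
}

#' @describeIn loadGenomeMap write a genome map back to the TSV dialect.
#' @param map a GenomeMap.
#' @export
writeGenomeMap <- function(map, path) {
    a <- map@anchors
    names(a) <- c("chrom", "pos_bp", "pos_cm")
    writeLines("chrom\tpos_bp\tpos_cm", path)
    utils::write.table(a, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE, append = TRUE)
    invisible(path)
}

#' @rdname GenomeMap-class
#' @export
setMethod("chromosomes", "GenomeMap", function(x) unique(x@anchors$chrom))

#' @rdname GenomeMap-class
#' @export
setMethod("chromLengthsBp", "GenomeMap", function(x) {
    vapply(split(x@anchors$bp, x@anchors$chrom), max, 0)[chromosomes(x)]
})

#' @rdname GenomeMap-class
#' @export
setMethod("chromLengthsCm", "GenomeMap", function(x) {
    vapply(split(x@anchors, x@anchors$chrom),
           function(a) max(a$cm) - min(a$cm), 0)[chromosomes(x)]
})

#' @rdname GenomeMap-class
#' @export
setMethod("totalCm", "GenomeMap", function(x) sum(chromLengthsCm(x)))

setMethod("show", "GenomeMap", function(object) {
    cat(sprintf("GenomeMap: %d chromosome(s), %.1f cM / %.1f Mb total\n",
                length(chromosomes(object)), totalCm(object),
                sum(chromLengthsBp(object)) / 1e6))
})

#' Convert physical to genetic coordinates
#'
#' Piecewise-linear interpolation of cM position between the flanking
#' anchors of the map. Positions outside the anchored range of a chromosome
#' are an error (never extrapolated, which would silently inflate segment
#' lengths).
#'
#' @param map a \code{GenomeMap}.
#' @param chrom chromosome identifier (scalar or vector recycled with
#'   \code{position_bp}).
#' @param position_bp physical position(s), 0-based.
#' @return genetic position(s) in cM.
#' @examples
#' m <- uniformGenomeMap("chr1", 1e8, 100)
#' bpToCm(m, "chr1", 5e7)  # 50
#' @export
bpToCm <- function(map, chrom, position_bp) {
    stopifnot(is(map, "GenomeMap"))
    n <- max(length(chrom), length(position_bp))
    chrom <- rep_len(as.character(chrom), n)
    position_bp <- rep_len(position_bp, n)
    out <- numeric(n)
    for (ch in unique(chrom)) {
        a <- map@anchors[map@anchors$chrom == ch, , drop = FALSE]
        if (nrow(a) == 0L) stop("chromosome not in map: ", ch)
        i <- which(chrom == ch)
        p <- position_bp[i]
        if (any(p < min(a$bp) | p > max(a$bp)))
            stop(sprintf("position outside chromosome %s [%g, %g]",
                         ch, min(a$bp), max(a$bp)))
        out[i] <- stats::approx(a$bp, a$cm, xout = p, ties = "ordered")$y
    }
    out
}

#' @describeIn bpToCm inverse interpolation, genetic to physical position.
#'   For maps with flat cM stretches the left-most bp of the stretch is
#'   returned.
#' @param position_cm genetic position(s) in cM.
#' @export
cmToBp <- function(map, chrom, position_cm) {
    stopifnot(is(map, "GenomeMap"))
    n <- max(length(chrom), length(position_cm))
    chrom <- rep_len(as.character(chrom), n)
    position_cm <- rep_len(position_cm, n)
    out <- numeric(n)
    for (ch in unique(chrom)) {
        a <- map@anchors[map@anchors$chrom == ch, , drop = FALSE]
        if (nrow(a) == 0L) stop("chromosome not in map: ", ch)
        i <- which(chrom == ch)
        p <- position_cm[i]
        if (any(p < min(a$cm) | p > max(a$cm)))
            stop(sprintf("cM position outside chromosome %s", ch))
        out[i] <- stats::approx(a$cm, a$bp, xout = p, ties = min)$y
    }
    out
}

# cM length of (chrom, start_bp, end_bp) intervals under the map
.intervalCm <- function(map, chrom, start_bp, end_bp) {
    bpToCm(map, chrom, end_bp) - bpToCm(map, chrom, start_bp)
}
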