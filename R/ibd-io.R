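#' Construct an IBDSegments object from raw columns
#'
#' Pairs are canonicalized (lexicographically smaller sample ID first,
#' swapping haplotype columns along with the samples) and genetic lengths
#' are computed from the genome map when one is supplied. Coordinates are
#' 0-based half-open.
#'
#' @param sample_a,sample_b sample IDs (equal IDs denote an HBD/ROH row).
#' @param chrom chromosome identifiers.
#' @param start_bp,end_bp 0-based half-open physical coordinates.
#' @param lod detection LOD scores.
#' @param hap_a,hap_b haplotype indices (1 or 2) from the detector; kept so
#'   files round-trip, defaulting to 1.
#' @param length_cm genetic lengths; computed via \code{map} when missing.
#' @param map optional \code{GenomeMap} used to compute \code{length_cm}.
#' @return an \code{\link[=IBDSegments-class]{IBDSegments}} object.
#' @export
IBDSegments <- function(sample_a, sample_b, chrom, start_bp, end_bp, lod,
                        hap_a = 1L, hap_b = 1L, length_cm = NULL, map = NULL) {
    n <- length(sample_a)
    sample_a <- as.character(sample_a); sample_b <- as.character(sample_b)
    hap_a <- rep_len(as.integer(hap_a), n); hap_b <- rep_len(as.integer(hap_b), n)
    swap <- sample_a > sample_b
    if (any(swap)) {
        tmp <- sample_a[swap]; sample_a[swap] <- sample_b[swap]; sample_b[swap] <- tmp
        tmph <- hap_a[swap]; hap_a[swap] <- hap_b[swap]; hap_b[swap] <- tmph
    }
    if (is.null(length_cm)) {
        if (is.null(map)) stop("supply either length_cm or a GenomeMap")
        length_cm <- .intervalCm(map, chrom, start_bp, end_bp)
    }
    seg <- data.frame(sample_a = sample_a, hap_a = hap_a,
                      sample_b = sample_b, hap_b = hap_b,
                      chrom = as.character(chrom),
                      start_bp = as.numeric(start_bp),
                      end_bp = as.numeric(end_bp),
                      length_cm = as.numeric(length_cm),
                      lod = as.numeric(lod),
                      hbd = sample_a == sample_b,
                      stringsAsFactors = FALSE)
    new("IBDSegments", seg = seg)
}

#' @rdname IBDSegments-class
#' @export
setMethod("segmentTable", "IBDSegments", function(x) x@seg)

#' @rdname IBDSegments-class
#' @export
setMethod("length", "IBDSegments", function(x) nrow(x@seg))

#' @rdname IBDSegments-class
#' @param i row index
#' @param j,drop,... unused
#' @export
setMethod("[", "IBDSegments", function(x, i, j, ..., drop = FALSE) {
    initialize(x, seg = x@seg[i, , drop = FALSE])
})

setMethod("show", "IBDSegments", function(object) {
    s <- object@seg
    cat(sprintf("IBDSegments: %d segment(s) (%d HBD) over %d sample(s)\n",
                nrow(s), sum(s$hbd),
                length(unique(c(s$sample_a, s$sample_b)))))
})

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
setAs("IBDSegments", "GRanges", function(from) {
    s <- from@seg
    GenomicRanges::GRanges(
        seqnames = s$chrom,
        ranges = IRanges::IRanges(start = s$start_bp + 1, end = s$end_bp),
        sample_a = s$sample_a, sample_b = s$sample_b,
        length_cm = s$length_cm, lod = s$lod, hbd = s$hbd)
})

#' Read IBD segments from an IBDseq-style TSV file
#'
#' The dialect has eight tab-separated columns: \code{sample1},
#' \code{haplotype1}, \code{sample2}, \code{haplotype2}, \code{chromosome},
#' \code{start}, \code{end}, \code{LOD}. Detector coordinates are read as
#' 0-based half-open (logged via message on first read). Rows with
#' \code{sample1 == sample2} are retained and marked HBD. Haplotype-level
#' rows between the same diploid pair are kept as separate segments.
#'
#' @param path path to the TSV (optionally with \code{#} comment lines and
#'   an optional header).
#' @param map a \code{GenomeMap}; cM lengths are computed for both segment
#'   endpoints through it.
#' @return an \code{IBDSegments} object in canonical pair order.
#' @export
readIBDSegments <- function(path, map) {
    first <- readLines(path, n = 50L)
    first <- first[!startsWith(first, "#")]
    has_header <- length(first) > 0 &&
        grepl("sample", strsplit(first[1], "\t")[[1]][1], ignore.case = TRUE)
    d <- utils::read.table(path, header = has_header, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(d) != 8L)
        stop("expected 8 tab-delimited columns (IBDseq dialect), got ", ncol(d))
    names(d) <- c("sample1", "haplotype1", "sample2", "haplotype2",
                  "chromosome", "start", "end", "LOD")
    if (any(d$end <= d$start)) stop("malformed row: end <= start")
    unknown <- setdiff(unique(as.character(d$chromosome)), chromosomes(map))
    if (length(unknown))
        stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    IBDSegments(sample_a = d$sample1, sample_b = d$sample2,
                hap_a = d$haplotype1, hap_b = d$haplotype2,
                chrom = d$chromosome, start_bp = d$start, end_bp = d$end,
                lod = d$LOD, map = map)
}

#' @describeIn readIBDSegments write segments back in the same dialect
#'   (header line prefixed with \code{#}).
#' @param x an \code{IBDSegments} object.
#' @export
writeIBDSegments <- function(x, path) {
    s <- segmentTable(x)
    out <- data.frame(sample1 = s$sample_a, haplotype1 = s$hap_a,
                      sample2 = s$sample_b, haplotype2 = s$hap_b,
                      chromosome = s$chrom, start = s$start_bp,
                      end = s$end_bp, LOD = s$lod)
    writeLines(paste0("#", paste(names(out), collapse = "\t")), path)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, append = TRUE)
    invisible(path)
}
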