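#' Summarize runs of homozygosity per individual
#'
#' From HBD segments (pre-filtered at the 1 cM ROH length cut-off),
#' computes each individual's total genetic length contained in long ROH
#' segments — those strictly longer than \code{long_cm} — and sets the
#' recent-parental-relatedness flag when that total strictly exceeds
#' \code{flag_cm}. Per-chromosome ROH totals over all supplied segments
#' are retained for uniparental-disomy screening.
#'
#' @param x an \code{IBDSegments} object; only HBD rows are used.
#' @param map a \code{GenomeMap}.
#' @param long_cm length class threshold in cM (strict), default 20.
#' @param flag_cm flag threshold on the long-ROH total (strict), default 50.
#' @param ids individuals to report; defaults to those with HBD segments.
#' @return list with \code{summary} — data.frame (id, total_long_cm,
#'   n_long, parental_flag) — and \code{per_chrom}, a matrix of ROH cM
#'   totals (individuals x chromosomes, all segments).
#' @export
summarizeROH <- function(x, map, long_cm = 20, flag_cm = 50, ids = NULL) {
    s <- segmentTable(x)
    s <- s[s$hbd, , drop = FALSE]
    if (is.null(ids)) ids <- sort(unique(s$sample_a))
    chroms <- chromosomes(map)
    per_chrom <- matrix(0, length(ids), length(chroms),
                        dimnames = list(ids, chroms))
    total_long <- stats::setNames(numeric(length(ids)), ids)
    n_long <- stats::setNames(integer(length(ids)), ids)
    s <- s[s$sample_a %in% ids, , drop = FALSE]
    if (nrow(s)) {
        agg <- rowsum(s$length_cm, paste(s$sample_a, s$chrom, sep = "\r"))
        key <- strsplit(rownames(agg), "\r", fixed = TRUE)
        for (k in seq_along(key))
            per_chrom[key[[k]][1], key[[k]][2]] <- agg[k, 1]
        long <- s[s$length_cm > long_cm, , drop = FALSE]
        if (nrow(long)) {
            tl <- rowsum(long$length_cm, long$sample_a)
            total_long[rownames(tl)] <- tl[, 1]
            nl <- table(long$sample_a)
            n_long[names(nl)] <- as.integer(nl)
        }
    }
    list(summary = data.frame(id = ids,
                              total_long_cm = as.numeric(total_long),
                              n_long = as.integer(n_long),
                              parental_flag = as.numeric(total_long) > flag_cm),
         per_chrom = per_chrom)
}

#' Screen for uniparental-disomy candidate chromosomes
#'
#' A chromosome is a UPD candidate for an individual when its ROH covers
#' at least \code{chrom_fraction} of the chromosome's genetic length while
#' the individual's ROH total over all other chromosomes stays below
#' \code{elsewhere_cm} — a whole-chromosome homozygosity signal without
#' genome-wide evidence of inbreeding. The thresholds operationalize an
#' observational criterion and are deliberately conservative heuristics.
#'
#' @param roh output of \code{\link{summarizeROH}}.
#' @param map a \code{GenomeMap}.
#' @param chrom_fraction minimum covered fraction of the chromosome
#'   (inclusive), default 0.9.
#' @param elsewhere_cm maximum ROH cM on the remaining chromosomes
#'   (strict), default 50.
#' @return data.frame (id, chrom, covered_fraction, elsewhere_cm), zero
#'   rows when no candidate is found.
#' @export
detectUPD <- function(roh, map, chrom_fraction = 0.9, elsewhere_cm = 50) {
    pc <- roh$per_chrom
    cm <- chromLengthsCm(map)[colnames(pc)]
    out <- list()
    for (id in rownames(pc)) {
        frac <- pc[id, ] / cm
        tot <- sum(pc[id, ])
        for (ch in colnames(pc)) {
            elsewhere <- tot - pc[id, ch]
            if (frac[[ch]] >= chrom_fraction && elsewhere < elsewhere_cm)
                out[[length(out) + 1L]] <- data.frame(
                    id = id, chrom = ch,
                    covered_fraction = frac[[ch]],
                    elsewhere_cm = elsewhere)
        }
    }
    if (length(out) == 0L)
        return(data.frame(id = character(0), chrom = character(0),
                          covered_fraction = numeric(0),
                          elsewhere_cm = numeric(0)))
    do.call(rbind, out)
}
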