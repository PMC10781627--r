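#' Joint genotype counts for a pair of individuals
#'
#' 3x3 table of alternate-allele dosage combinations over sites that are
#' non-missing in both individuals (and inside the optional site mask).
#' These counts are the sufficient statistics of the allele-frequency-free
#' relatedness estimators.
#'
#' @param gi,gj integer genotype vectors in \{0, 1, 2\} with NA allowed;
#'   equal length.
#' @param site_mask optional logical vector selecting sites.
#' @return list with \code{counts} (3x3 matrix, rows = gi, cols = gj) and
#'   \code{n} (contributing sites).
#' @export
jointCounts <- function(gi, gj, site_mask = NULL) {
    if (length(gi) != length(gj)) stop("genotype vector length mismatch")
    keep <- !is.na(gi) & !is.na(gj)
    if (!is.null(site_mask)) keep <- keep & site_mask
    cnt <- table(factor(gi[keep], levels = 0:2),
                 factor(gj[keep], levels = 0:2))
    counts <- matrix(as.numeric(cnt), 3, 3,
                     dimnames = list(gi = 0:2, gj = 0:2))
    list(counts = counts, n = sum(counts))
}

#' Allele-frequency-free relatedness estimators
#'
#' Computes, from the joint genotype counts of a pair, with
#' O = opposing homozygotes, H = double heterozygotes, D = all discordant
#' (off-diagonal) pairs, and het_i/het_j the per-individual heterozygous
#' site totals:
#' \deqn{R0 = O / H, \quad R1 = H / D, \quad
#'       KING = (H - 2 O) / (het_i + het_j)}
#' A zero denominator makes the corresponding estimator NA (the pair is
#' then not classifiable). Duplicate genomes give KING = 0.5 and R0 = 0;
#' parent-offspring pairs give R0 = 0 by Mendelian constraint.
#'
#' @param jc output of \code{\link{jointCounts}}.
#' @return list with \code{R0}, \code{R1}, \code{king}, \code{n_sites}.
#' @export
kinshipEstimators <- function(jc) {
    N <- jc$counts
    O <- N["0", "2"] + N["2", "0"]
    H <- N["1", "1"]
    D <- sum(N) - sum(diag(N))
    het_i <- sum(N["1", ]); het_j <- sum(N[, "1"])
    list(R0 = if (H > 0) O / H else NA_real_,
         R1 = if (D > 0) H / D else NA_real_,
         king = if (het_i + het_j > 0) (H - 2 * O) / (het_i + het_j)
                else NA_real_,
         n_sites = jc$n)
}

# KING-robust kinship degree cut-offs: powers-of-two convention
.KING_CUTS <- 2^(-c(3, 5, 7, 9) / 2)

#' Classify a pair's relationship
#'
#' Pairs with fewer than \code{min_sites} contributing sites (or missing
#' estimator values) are excluded. Degrees follow the established
#' KING-robust cut-offs: kinship > 2^(-3/2) duplicate/MZ; (2^(-5/2),
#' 2^(-3/2)] first degree; (2^(-7/2), 2^(-5/2)] second; (2^(-9/2),
#' 2^(-7/2)] third; otherwise unrelated. First-degree pairs are called
#' parent-offspring iff R0 <= 0.02 and 0.4 <= R1 <= 0.6, and
#' full-sibling/other-first-degree otherwise.
#'
#' @param est list from \code{\link{kinshipEstimators}}.
#' @param min_sites minimum contributing sites, default 20000.
#' @param cutoffs numeric length-4 decreasing vector of KING degree
#'   boundaries.
#' @param po_r0_max,po_r1_range parent-offspring rule thresholds.
#' @return relationship call string.
#' @export
classifyPair <- function(est, min_sites = 20000, cutoffs = .KING_CUTS,
                         po_r0_max = 0.02, po_r1_range = c(0.4, 0.6)) {
    if (est$n_sites < min_sites) return("excluded")
    if (is.na(est$king)) return("excluded")
    k <- est$king
    if (k > cutoffs[1]) return("duplicate_MZ")
    if (k > cutoffs[2]) {
        po <- !is.na(est$R0) && !is.na(est$R1) &&
            est$R0 <= po_r0_max &&
            est$R1 >= po_r1_range[1] && est$R1 <= po_r1_range[2]
        return(if (po) "parent_offspring" else "full_sibling_other_1st")
    }
    if (k > cutoffs[3]) return("second_degree")
    if (k > cutoffs[4]) return("third_degree")
    "unrelated"
}

#' Pairwise kinship table for a genotype matrix
#'
#' Runs \code{\link{jointCounts}}, \code{\link{kinshipEstimators}} and
#' \code{\link{classifyPair}} over every sample pair.
#'
#' @param geno integer matrix, sites x samples, dosages in \{0, 1, 2\}
#'   with NA allowed; column names are sample IDs.
#' @param site_mask optional logical site selector.
#' @param ... passed to \code{\link{classifyPair}}.
#' @return data.frame (sample_a, sample_b, R0, R1, king, n_sites, call)
#'   with pairs in canonical order.
#' @export
kinshipTable <- function(geno, site_mask = NULL, ...) {
    ids <- colnames(geno)
    stopifnot(!is.null(ids))
    out <- list()
    for (i in seq_len(ncol(geno) - 1)) for (j in seq(i + 1, ncol(geno))) {
        a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
        est <- kinshipEstimators(jointCounts(geno[, i], geno[, j], site_mask))
        out[[length(out) + 1L]] <- data.frame(
            sample_a = a, sample_b = b,
            R0 = est$R0, R1 = est$R1, king = est$king,
            n_sites = est$n_sites, call = classifyPair(est, ...))
    }
    do.call(rbind, out)
}

#' Flag the lower-quality member of close relative pairs
#'
#' Within each first-degree (including duplicate) or second-degree pair,
#' the member with the lower autosomal coverage receives a \code{1d_rel}
#' or \code{2d_rel} flag; ties are broken deterministically by flagging
#' the lexicographically larger sample ID. The flags feed
#' \code{\link{applySampleFilters}} unchanged.
#'
#' @param kin data.frame from \code{\link{kinshipTable}}.
#' @param coverage named numeric vector, autosomal coverage per sample.
#' @return data.frame (id, flag), zero rows when no close pairs exist.
#' @export
flagLowerQualityRelative <- function(kin, coverage) {
    first <- c("duplicate_MZ", "parent_offspring", "full_sibling_other_1st")
    out <- list()
    for (r in seq_len(nrow(kin))) {
        call <- kin$call[r]
        fl <- if (call %in% first) "1d_rel"
              else if (call == "second_degree") "2d_rel" else NA_character_
        if (is.na(fl)) next
        a <- kin$sample_a[r]; b <- kin$sample_b[r]
        ca <- coverage[[a]]; cb <- coverage[[b]]
        lower <- if (ca < cb) a else if (cb < ca) b else max(a, b)
        out[[length(out) + 1L]] <- data.frame(id = lower, flag = fl)
    }
    if (length(out) == 0L)
        return(data.frame(id = character(0), flag = character(0)))
    unique(do.call(rbind, out))
}

#' Read a genotype matrix from TSV or VCF text
#'
#' TSV: sites x samples dosage matrix with a header of sample IDs and
#' optional leading \code{chrom}/\code{pos} columns. VCF: uncompressed
#' text, diploid GT field only; alleles are summed to dosages and
#' \code{./.} becomes NA.
#'
#' @param path input path; format chosen by extension (\code{.vcf} vs
#'   anything else as TSV).
#' @return integer matrix, sites x samples.
#' @export
readGenotypeMatrix <- function(path) {
    if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
        ln <- readLines(path)
        hdr <- ln[startsWith(ln, "#CHROM")]
        if (length(hdr) != 1L) stop("malformed VCF: missing #CHROM header")
        cols <- strsplit(hdr, "\t")[[1]]
        ids <- cols[-(1:9)]
        body <- ln[!startsWith(ln, "#")]
        rows <- strsplit(body, "\t")
        gt <- t(vapply(rows, function(r) {
            g <- sub(":.*", "", r[-(1:9)])
            a <- suppressWarnings(
                as.integer(substr(g, 1, 1)) + as.integer(substr(g, 3, 3)))
            a
        }, integer(length(ids))))
        colnames(gt) <- ids
        return(gt)
    }
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE)
    d <- d[, setdiff(names(d), c("chrom", "pos")), drop = FALSE]
    as.matrix(d)
}
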