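#' Sample-level QC flags
#'
#' Flags individuals to potentially exclude from downstream analyses.
#' The flag vocabulary is fixed and closed:
#' \describe{
#'   \item{contMT5pct / contNuc5pct}{mitochondrial / nuclear contamination
#'     estimate greater than 5\%}
#'   \item{lowcov}{autosomal coverage less than 0.1x}
#'   \item{lowGpAvg}{genome-wide mean imputation genotype probability less
#'     than 0.98}
#'   \item{1d_rel / 2d_rel}{lower-quality member of a first- / second-degree
#'     relative pair (set by \code{\link{flagLowerQualityRelative}} and
#'     merged here)}
#' }
#' An individual passes all filters iff no flag is set. Missing metric
#' fields leave the corresponding flag unset (logged via message).
#'
#' @param samples data.frame of sample records with column \code{id} and
#'   any of \code{contamination_mt}, \code{contamination_nuc} (percent),
#'   \code{autosomal_coverage} (fold), \code{mean_genotype_probability}.
#' @param relative_flags optional data.frame (\code{id}, \code{flag}) from
#'   \code{\link{flagLowerQualityRelative}}.
#' @param thresholds list with elements \code{contamination_pct} (5),
#'   \code{min_coverage} (0.1), \code{min_gp} (0.98).
#' @return the input with added columns \code{qc_flags} (comma-separated,
#'   \code{""} when clean) and logical \code{pass}.
#' @examples
#' s <- data.frame(id = "a", contamination_nuc = 6, autosomal_coverage = 1,
#'                 mean_genotype_probability = 0.99)
#' applySampleFilters(s)$qc_flags
#' @export
applySampleFilters <- function(samples, relative_flags = NULL,
                               thresholds = list(contamination_pct = 5,
                                                 min_coverage = 0.1,
                                                 min_gp = 0.98)) {
    stopifnot("id" %in% names(samples))
    n <- nrow(samples)
    flags <- vector("list", n)
    getcol <- function(nm) if (nm %in% names(samples)) samples[[nm]] else {
        message("column '", nm, "' missing; flag left unset")
        rep(NA_real_, n)
    }
    cmt <- getcol("contamination_mt")
    cnu <- getcol("contamination_nuc")
    cov <- getcol("autosomal_coverage")
    gp  <- getcol("mean_genotype_probability")
    add <- function(cond, flag) {
        hit <- which(!is.na(cond) & cond)
        for (i in hit) flags[[i]] <<- c(flags[[i]], flag)
    }
    add(cmt > thresholds$contamination_pct, "contMT5pct")
    add(cnu > thresholds$contamination_pct, "contNuc5pct")
    add(cov < thresholds$min_coverage, "lowcov")
    add(gp < thresholds$min_gp, "lowGpAvg")
    if (!is.null(relative_flags) && nrow(relative_flags)) {
        stopifnot(all(relative_flags$flag %in% c("1d_rel", "2d_rel")))
        for (k in seq_len(nrow(relative_flags))) {
            i <- which(samples$id == relative_flags$id[k])
            for (j in i) flags[[j]] <- c(flags[[j]], relative_flags$flag[k])
        }
    }
    vocab <- c("contMT5pct", "contNuc5pct", "lowcov", "lowGpAvg",
               "1d_rel", "2d_rel")
    samples$qc_flags <- vapply(flags, function(f) {
        paste(intersect(vocab, unique(f)), collapse = ",")
    }, "")
    samples$pass <- samples$qc_flags == ""
    samples
}

#' Read a sample metadata TSV
#'
#' Tab-delimited with a header (optionally \code{#}-prefixed); expected
#' columns are \code{id}, \code{age_bp}, \code{latitude}, \code{longitude},
#' \code{group_label} plus the QC metric columns used by
#' \code{\link{applySampleFilters}}.
#'
#' @param path path to the TSV.
#' @return a data.frame.
#' @export
readSampleMetadata <- function(path) {
    ln <- readLines(path)
    if (length(ln) && startsWith(ln[1], "#")) ln[1] <- sub("^#", "", ln[1])
    utils::read.table(text = ln, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
}

#' @describeIn readSampleMetadata write metadata with a \code{#}-prefixed
#'   header line.
#' @param samples data.frame of sample records.
#' @export
writeSampleMetadata <- function(samples, path) {
    writeLines(paste0("#", paste(names(samples), collapse = "\t")), path)
    utils::write.table(samples, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, append = TRUE)
    invisible(path)
}
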