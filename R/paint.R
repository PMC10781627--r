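#' Per-donor-group IBD totals for one individual
#'
#' Sums the cM lengths of IBD segments between \code{ind} and every member
#' of each donor group, per chromosome. The individual itself is always
#' excluded (leave-one-out: a recipient cannot act as a donor from its own
#' group), and further samples can be excluded via \code{exclude}. HBD
#' rows never contribute.
#'
#' @param ind sample ID of the painted individual.
#' @param x QC-filtered \code{IBDSegments}.
#' @param donors named character vector mapping donor sample ID to donor
#'   group label; every donor belongs to exactly one group.
#' @param map a \code{GenomeMap}.
#' @param exclude additional sample IDs excluded as donors.
#' @return numeric matrix, donor groups x chromosomes, of cM totals.
#' @export
paintingTotals <- function(ind, x, donors, map, exclude = character(0)) {
    s <- segmentTable(x)
    s <- s[!s$hbd & (s$sample_a == ind | s$sample_b == ind), , drop = FALSE]
    partner <- ifelse(s$sample_a == ind, s$sample_b, s$sample_a)
    keep <- partner %in% names(donors) & !(partner %in% c(ind, exclude))
    s <- s[keep, , drop = FALSE]; partner <- partner[keep]
    groups <- sort(unique(donors))
    chroms <- chromosomes(map)
    tot <- matrix(0, length(groups), length(chroms),
                  dimnames = list(groups, chroms))
    if (nrow(s)) {
        agg <- rowsum(s$length_cm,
                      paste(donors[partner], s$chrom, sep = "\r"))
        key <- strsplit(rownames(agg), "\r", fixed = TRUE)
        for (k in seq_along(key))
            tot[key[[k]][1], key[[k]][2]] <- agg[k, 1]
    }
    tot
}

# normalize per-chromosome totals into a genome-wide profile vector,
# optionally deleting one chromosome (block jackknife)
.profileFromTotals <- function(totals, drop_chrom = NULL) {
    keep <- setdiff(colnames(totals), drop_chrom)
    v <- rowSums(totals[, keep, drop = FALSE])
    tot <- sum(v)
    if (tot <= 0) return(NULL)
    v / tot
}

#' Leave-one-out IBD painting profile
#'
#' The painting profile of a target individual is the vector of total IBD
#' sharing with each donor group, normalized to sum to 1. Targets sharing
#' no IBD with any donor have no profile; this is an error rather than a
#' silent zero vector.
#'
#' @inheritParams paintingTotals
#' @param target sample ID of the target.
#' @return list with \code{target}, \code{profile} (named, sums to 1) and
#'   \code{totals_cm} (groups x chromosomes, un-normalized).
#' @export
paintingProfile <- function(target, x, donors, map, exclude = character(0)) {
    tot <- paintingTotals(target, x, donors, map, exclude)
    p <- .profileFromTotals(tot)
    if (is.null(p))
        stop("target ", target, " shares no IBD with any donor; no profile")
    list(target = target, profile = p, totals_cm = tot)
}

#' Mean painting profiles of source groups
#'
#' Column g is the mean of the leave-one-out profiles of group g's
#' members; columns sum to 1. Members without a valid profile are dropped
#' with a message; an entirely empty source group is an error.
#'
#' @param source_groups character vector of source group labels (must
#'   occur in \code{donors}).
#' @inheritParams paintingTotals
#' @param drop_chrom optional chromosome deleted before normalization
#'   (block jackknife support).
#' @param member_totals optional precomputed list (sample ID ->
#'   totals matrix from \code{\link{paintingTotals}}) to avoid
#'   recomputation.
#' @return matrix, donor groups x source groups.
#' @export
sourceProfiles <- function(source_groups, x, donors, map,
                           drop_chrom = NULL, member_totals = NULL) {
    bad <- setdiff(source_groups, donors)
    if (length(bad))
        stop("unknown source group(s): ", paste(bad, collapse = ", "))
    groups <- sort(unique(donors))
    S <- matrix(0, length(groups), length(source_groups),
                dimnames = list(groups, source_groups))
    for (g in source_groups) {
        members <- names(donors)[donors == g]
        profs <- list()
        for (mem in members) {
            tot <- if (!is.null(member_totals)) member_totals[[mem]]
                   else paintingTotals(mem, x, donors, map)
            p <- .profileFromTotals(tot, drop_chrom)
            if (!is.null(p)) profs[[mem]] <- p
        }
        if (length(profs) == 0L)
            stop("source group ", g, " has no member with a valid profile")
        S[, g] <- rowMeans(do.call(cbind, profs))
    }
    S
}

#' Simplex-constrained non-negative least squares
#'
#' Solves min || S w - p ||_2 subject to w >= 0 and sum(w) = 1. The
#' sum-to-one condition is a hard equality constraint (not a post-hoc
#' renormalization): the solver enumerates candidate support sets, solves
#' the equality-constrained normal equations on each via its KKT system,
#' and returns the feasible solution with the smallest residual. Exact for
#' the small source panels used in supervised ancestry modelling.
#'
#' @param S numeric matrix (donor groups x sources); no all-zero columns.
#' @param p numeric target profile vector, length nrow(S).
#' @return list with \code{w} (named proportions, sum 1), \code{residual}
#'   (Euclidean norm of S w - p).
#' @export
simplexNNLS <- function(S, p) {
    S <- as.matrix(S)
    k <- ncol(S)
    if (k == 0L) stop("no sources")
    if (any(colSums(abs(S)) == 0)) stop("degenerate source matrix: all-zero column")
    if (length(p) != nrow(S)) stop("profile/source row mismatch")
    if (k > 15L) stop("support enumeration solver limited to <= 15 sources")
    StS <- crossprod(S); Stp <- crossprod(S, p)
    best <- NULL
    for (mask in seq_len(2^k - 1L)) {
        A <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
        m <- length(A)
        K <- rbind(cbind(StS[A, A, drop = FALSE], rep(1, m)),
                   c(rep(1, m), 0))
        sol <- tryCatch(solve(K, c(Stp[A], 1)), error = function(e) NULL)
        if (is.null(sol)) next
        wA <- sol[seq_len(m)]
        if (any(wA < -1e-9)) next
        wA[wA < 0] <- 0
        wA <- wA / sum(wA)
        w <- stats::setNames(numeric(k), colnames(S))
        w[A] <- wA
        resid <- sqrt(sum((S %*% w - p)^2))
        if (is.null(best) || resid < best$residual - 1e-12)
            best <- list(w = w, residual = resid)
    }
    if (is.null(best)) stop("no feasible support found (singular source matrix)")
    best
}

#' Supervised ancestry fit of one target
#'
#' Models the target's painting profile as a non-negative, sum-to-one
#' mixture of source-group profiles by constrained least squares.
#'
#' @param target_profile named numeric profile vector (sums to 1).
#' @param source_matrix matrix from \code{\link{sourceProfiles}}, rows
#'   aligned with \code{target_profile}.
#' @return list with \code{proportions}, \code{residual}.
#' @export
fitAncestry <- function(target_profile, source_matrix) {
    stopifnot(length(target_profile) == nrow(source_matrix))
    fit <- simplexNNLS(source_matrix, target_profile)
    list(proportions = fit$w, residual = fit$residual)
}

#' Weighted block jackknife standard errors of ancestry proportions
#'
#' Leaves out each chromosome in turn, rebuilds the target and source
#' profiles without it, re-fits, and combines the delete-one estimates
#' with block weights proportional to the cM length of the deleted
#' chromosome, using the standard weighted delete-one jackknife variance
#' formula.
#'
#' @param target_totals target per-chromosome totals matrix
#'   (\code{\link{paintingTotals}}).
#' @param source_groups character vector of source group labels.
#' @param x,donors,map as in \code{\link{paintingTotals}}.
#' @param member_totals optional precomputed member totals list.
#' @return list with \code{se} (per source), \code{proportions} (full-data
#'   fit), \code{residual}, and \code{loo} (matrix of delete-one
#'   estimates, chromosomes x sources).
#' @export
jackknifeSE <- function(target_totals, source_groups, x, donors, map,
                        member_totals = NULL) {
    chroms <- chromosomes(map)
    if (length(chroms) < 2L) stop("block jackknife needs >= 2 chromosomes")
    if (is.null(member_totals)) {
        member_totals <- lapply(
            stats::setNames(nm = names(donors)[donors %in% source_groups]),
            paintingTotals, x = x, donors = donors, map = map)
    }
    S_full <- sourceProfiles(source_groups, x, donors, map,
                             member_totals = member_totals)
    p_full <- .profileFromTotals(target_totals)
    if (is.null(p_full)) stop("empty target profile")
    fit_full <- simplexNNLS(S_full, p_full)
    theta <- fit_full$w
    cm <- chromLengthsCm(map)
    loo <- matrix(NA_real_, length(chroms), length(source_groups),
                  dimnames = list(chroms, source_groups))
    used <- character(0)
    for (ch in chroms) {
        p_c <- .profileFromTotals(target_totals, drop_chrom = ch)
        if (is.null(p_c)) { warning("no sharing outside ", ch, "; block skipped"); next }
        S_c <- sourceProfiles(source_groups, x, donors, map, drop_chrom = ch,
                              member_totals = member_totals)
        loo[ch, ] <- simplexNNLS(S_c, p_c)$w
        used <- c(used, ch)
    }
    g <- length(used)
    if (g < 2L) stop("fewer than 2 usable jackknife blocks")
    m <- cm[used]; n <- sum(m)
    h <- n / m
    # Busing-style weighted delete-one jackknife
    theta_J <- g * theta - colSums((1 - m / n) * loo[used, , drop = FALSE])
    tau <- t(h * matrix(theta, g, length(theta), byrow = TRUE) -
             (h - 1) * loo[used, , drop = FALSE])
    v <- rowSums((tau - theta_J)^2 / matrix(h - 1, length(theta), g,
                                            byrow = TRUE)) / g
    list(se = sqrt(pmax(v, 0)), proportions = theta,
         residual = fit_full$residual, loo = loo)
}

#' Fit targets against named source sets
#'
#' Runs the supervised ancestry model for every target against each named
#' panel of source groups (for example panels of different temporal
#' depths), with jackknife standard errors; fits are comparable across
#' panels through the residual norm.
#'
#' @param targets character vector of target sample IDs.
#' @param source_sets named list; each element a character vector of
#'   source group labels present in \code{donors}.
#' @param x,donors,map as in \code{\link{paintingTotals}}.
#' @param se compute jackknife standard errors (default TRUE).
#' @return data.frame (target, set, source, proportion, se, residual).
#' @export
fitSourceSets <- function(targets, source_sets, x, donors, map, se = TRUE) {
    stopifnot(length(names(source_sets)) == length(source_sets))
    all_src <- unique(unlist(source_sets))
    bad <- setdiff(all_src, donors)
    if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
    member_totals <- lapply(
        stats::setNames(nm = names(donors)[donors %in% all_src]),
        paintingTotals, x = x, donors = donors, map = map)
    out <- list()
    for (tg in targets) {
        tt <- paintingTotals(tg, x, donors, map)
        for (nm in names(source_sets)) {
            src <- source_sets[[nm]]
            if (se) {
                f <- jackknifeSE(tt, src, x, donors, map,
                                 member_totals = member_totals)
                ses <- f$se
            } else {
                S <- sourceProfiles(src, x, donors, map,
                                    member_totals = member_totals)
                p <- .profileFromTotals(tt)
                if (is.null(p)) stop("target ", tg, " has an empty profile")
                f <- simplexNNLS(S, p)
                f$proportions <- f$w
                ses <- rep(NA_real_, length(src))
            }
            out[[length(out) + 1L]] <- data.frame(
                target = tg, set = nm, source = src,
                proportion = as.numeric(f$proportions[src]),
                se = as.numeric(ses[src]),
                residual = f$residual)
        }
    }
    do.call(rbind, out)
}
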