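#' Simulate a cohort of IBD segments with planted cluster structure
#'
#' Generates pairwise IBD segment lists for a cohort of grouped
#' individuals plus optional admixed targets with known mixture vectors.
#' Pairwise segment counts are Poisson: rate \code{lambda_in} within a
#' group, \code{lambda_out} between groups, and \code{w_g * lambda_in}
#' between an admixed target and members of group g (so the expected
#' painting profile of a target is its mixture vector by construction).
#' Segment lengths are exponential with mean \code{mean_cm}, truncated
#' below at \code{min_cm} (the generator only emits post-QC-threshold
#' segments); positions are uniform on the genetic map; LOD scores are
#' drawn above the passing threshold. Pure function of the spec and seed.
#'
#' @param spec list with \code{groups} (named integer vector of group
#'   sizes), \code{lambda_in}, \code{lambda_out}, \code{mean_cm} (default
#'   3), \code{min_cm} (default 2), \code{targets} (named list of mixture
#'   vectors over group names, may be empty), \code{map} (a
#'   \code{GenomeMap}), \code{seed} (mandatory), optional \code{min_lod}
#'   (default 3).
#' @return list with \code{segments} (\code{IBDSegments}), \code{truth}
#'   (data.frame id, group — targets labelled \code{"admixed"}) and
#'   \code{mixtures} (targets x groups matrix of true proportions).
#' @export
simulateGroupIBD <- function(spec) {
    stopifnot(!is.null(spec$seed), !is.null(spec$groups), !is.null(spec$map))
    lambda_in <- spec$lambda_in; lambda_out <- spec$lambda_out
    stopifnot(lambda_in > lambda_out, lambda_out >= 0)
    mean_cm <- if (is.null(spec$mean_cm)) 3 else spec$mean_cm
    min_cm <- if (is.null(spec$min_cm)) 2 else spec$min_cm
    min_lod <- if (is.null(spec$min_lod)) 3 else spec$min_lod
    stopifnot(mean_cm > min_cm)
    map <- spec$map
    targets <- if (is.null(spec$targets)) list() else spec$targets
    for (w in targets)
        stopifnot(all(w >= 0), abs(sum(w) - 1) < 1e-9,
                  all(names(w) %in% names(spec$groups)))
    set.seed(spec$seed)
    gnames <- names(spec$groups)
    ids <- unlist(lapply(gnames, function(g)
        sprintf("%s_%02d", g, seq_len(spec$groups[[g]]))))
    grp <- rep(gnames, spec$groups)
    tids <- names(targets)
    all_ids <- c(ids, tids)
    all_grp <- c(grp, rep("admixed", length(tids)))
    truth <- data.frame(id = all_ids, group = all_grp)
    mix <- matrix(0, length(tids), length(gnames),
                  dimnames = list(tids, gnames))
    for (tg in tids) mix[tg, names(targets[[tg]])] <- targets[[tg]]

    cmlen <- chromLengthsCm(map)
    chroms <- names(cmlen)
    n <- length(all_ids)
    pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
    pair_j <- unlist(lapply(seq_len(n - 1), function(i) seq(i + 1, n)))
    rate <- numeric(length(pair_i))
    for (k in seq_along(pair_i)) {
        gi <- all_grp[pair_i[k]]; gj <- all_grp[pair_j[k]]
        rate[k] <-
            if (gi == "admixed" && gj == "admixed") lambda_out
            else if (gi == "admixed") mix[all_ids[pair_i[k]], gj] * lambda_in
            else if (gj == "admixed") mix[all_ids[pair_j[k]], gi] * lambda_in
            else if (gi == gj) lambda_in else lambda_out
    }
    counts <- stats::rpois(length(rate), rate)
    tot <- sum(counts)
    rows <- vector("list", tot)
    r <- 0L
    for (k in which(counts > 0)) {
        for (s in seq_len(counts[k])) {
            len <- NA
            for (try in seq_len(100L)) {
                len <- min_cm + stats::rexp(1, rate = 1 / (mean_cm - min_cm))
                fits <- cmlen >= len
                if (any(fits)) break
                len <- NA
            }
            if (is.na(len)) stop("genome too short to place drawn segment")
            ch <- sample(chroms[cmlen >= len], 1,
                         prob = cmlen[cmlen >= len])
            st_cm <- stats::runif(1, 0, cmlen[[ch]] - len)
            r <- r + 1L
            rows[[r]] <- data.frame(
                a = all_ids[pair_i[k]], b = all_ids[pair_j[k]],
                chrom = ch, start_cm = st_cm, end_cm = st_cm + len,
                lod = min_lod + stats::rexp(1, rate = 0.2),
                hap_a = sample(1:2, 1), hap_b = sample(1:2, 1))
        }
    }
    if (r == 0L) {
        seg <- IBDSegments(character(0), character(0), character(0),
                           numeric(0), numeric(0), numeric(0),
                           length_cm = numeric(0))
        return(list(segments = seg, truth = truth, mixtures = mix))
    }
    d <- do.call(rbind, rows)
    start_bp <- cmToBp(map, d$chrom, d$start_cm)
    end_bp <- cmToBp(map, d$chrom, d$end_cm)
    # guard against flat-map degeneracies collapsing an interval
    end_bp <- pmax(end_bp, start_bp + 1)
    seg <- IBDSegments(sample_a = d$a, sample_b = d$b, chrom = d$chrom,
                       start_bp = round(start_bp), end_bp = round(end_bp),
                       lod = d$lod, hap_a = d$hap_a, hap_b = d$hap_b,
                       map = map)
    list(segments = seg, truth = truth, mixtures = mix)
}

# place n_sites site positions over the map, density uniform in bp
.simSites <- function(map, n_sites) {
    bp <- chromLengthsBp(map)
    per <- stats::setNames(pmax(1L, round(n_sites * bp / sum(bp))), names(bp))
    rows <- lapply(names(bp), function(ch) {
        pos <- sort(stats::runif(per[[ch]], 0, bp[[ch]]))
        data.frame(chrom = ch, pos_bp = pos,
                   pos_cm = bpToCm(map, ch, pos))
    })
    do.call(rbind, rows)
}

# one meiosis: recombine two parental haplotypes along the cM map.
# haplotypes are lists with $allele and $origin vectors over all sites.
.meiosis <- function(h1, h2, sites) {
    allele <- integer(nrow(sites)); origin <- integer(nrow(sites))
    for (ch in unique(sites$chrom)) {
        i <- which(sites$chrom == ch)
        cm <- sites$pos_cm[i]
        L <- max(cm) - min(cm)
        k <- stats::rpois(1, L / 100)
        xo <- sort(stats::runif(k, min(cm), max(cm)))
        phase <- (findInterval(cm, xo) + sample(0:1, 1)) %% 2L
        allele[i] <- ifelse(phase == 0L, h1$allele[i], h2$allele[i])
        origin[i] <- ifelse(phase == 0L, h1$origin[i], h2$origin[i])
    }
    list(allele = allele, origin = origin)
}

# haplotype-level IBD tracts between two individuals from origin vectors
.trueIBDPair <- function(ind_a, ind_b, id_a, id_b, sites, map) {
    rows <- list()
    for (ha in 1:2) for (hb in 1:2) {
        oa <- ind_a[[ha]]$origin; ob <- ind_b[[hb]]$origin
        same <- oa == ob
        for (ch in unique(sites$chrom)) {
            i <- which(sites$chrom == ch)
            rl <- rle(same[i])
            ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
            for (k in which(rl$values)) {
                i0 <- i[starts[k]]; i1 <- i[ends[k]]
                if (sites$pos_cm[i1] <= sites$pos_cm[i0]) next
                rows[[length(rows) + 1L]] <- data.frame(
                    a = id_a, b = id_b, ha = ha, hb = hb, chrom = ch,
                    start_bp = sites$pos_bp[i0], end_bp = sites$pos_bp[i1])
            }
        }
    }
    if (length(rows) == 0L) return(NULL)
    do.call(rbind, rows)
}

#' Simulate pedigree genotypes with known relationships
#'
#' Gene-dropping simulator: founder haplotypes are drawn site-wise from an
#' allele-frequency model (MAF uniform on \code{maf_range}), and offspring
#' are produced by meioses with Poisson-distributed crossovers on the cM
#' map. Each requested relationship is realized in its own independent
#' mini-pedigree (duplicate, parent-offspring, full siblings, half
#' siblings for second degree, first cousins for third degree, or two
#' unrelated founders), so cross-pedigree pairs are unrelated. True IBD
#' segments are recorded from the transmitted founder-haplotype tracts of
#' each focal pair.
#'
#' @param spec list with \code{relationships} (named integer vector over
#'   \code{duplicate}, \code{parent_offspring}, \code{full_sibling},
#'   \code{second_degree}, \code{third_degree}, \code{unrelated}),
#'   \code{n_sites}, \code{maf_range} (default c(0.05, 0.5)), \code{map},
#'   \code{seed}, optional \code{record_ibd} (default TRUE; FALSE skips
#'   tract extraction for speed).
#' @return list with \code{geno} (sites x individuals dosage matrix),
#'   \code{truth} (data.frame sample_a, sample_b, relationship over focal
#'   pairs, canonical order), \code{pedigree} (id, mother, father; NA for
#'   founders), \code{sites} (chrom, pos_bp, pos_cm, maf) and
#'   \code{true_ibd} (\code{IBDSegments} of focal-pair tracts).
#' @export
simulatePedigreeCohort <- function(spec) {
    stopifnot(!is.null(spec$seed), !is.null(spec$map), spec$n_sites > 0)
    maf_range <- if (is.null(spec$maf_range)) c(0.05, 0.5) else spec$maf_range
    stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5)
    set.seed(spec$seed)
    map <- spec$map
    sites <- .simSites(map, spec$n_sites)
    sites$maf <- stats::runif(nrow(sites), maf_range[1], maf_range[2])
    ns <- nrow(sites)
    counter <- new.env(); counter$hap <- 0L
    founder <- function() {
        h <- function() {
            counter$hap <- counter$hap + 1L
            list(allele = stats::rbinom(ns, 1L, sites$maf),
                 origin = rep(counter$hap, ns))
        }
        list(h(), h())
    }
    child <- function(mo, fa) list(.meiosis(mo[[1]], mo[[2]], sites),
                                   .meiosis(fa[[1]], fa[[2]], sites))
    inds <- list(); ped <- list()
    addind <- function(id, hp, mother = NA, father = NA) {
        inds[[id]] <<- hp
        ped[[length(ped) + 1L]] <<- data.frame(id = id, mother = mother,
                                               father = father)
    }
    record <- if (is.null(spec$record_ibd)) TRUE else spec$record_ibd
    pairs <- list(); ibd <- list()
    addpair <- function(a, b, rel, record_ibd = record) {
        pairs[[length(pairs) + 1L]] <<- data.frame(
            sample_a = min(a, b), sample_b = max(a, b), relationship = rel)
        if (record_ibd) {
            tr <- .trueIBDPair(inds[[a]], inds[[b]], min(a, b), max(a, b),
                               sites, map)
            if (!is.null(tr)) ibd[[length(ibd) + 1L]] <<- tr
        }
    }
    rels <- spec$relationships
    for (rel in names(rels)) for (r in seq_len(rels[[rel]])) {
        tag <- sprintf("%s%d", toupper(substr(rel, 1, 2)), r)
        if (rel == "duplicate") {
            a <- paste0(tag, "_a"); b <- paste0(tag, "_b")
            f <- founder(); addind(a, f); addind(b, f)
            addpair(a, b, rel)
        } else if (rel == "parent_offspring") {
            m <- paste0(tag, "_p"); f2 <- paste0(tag, "_f")
            o <- paste0(tag, "_o")
            mo <- founder(); fa <- founder()
            addind(m, mo); addind(f2, fa)
            addind(o, child(mo, fa), mother = m, father = f2)
            addpair(m, o, rel)
        } else if (rel == "full_sibling") {
            m <- paste0(tag, "_m"); f2 <- paste0(tag, "_f")
            a <- paste0(tag, "_a"); b <- paste0(tag, "_b")
            mo <- founder(); fa <- founder()
            addind(m, mo); addind(f2, fa)
            addind(a, child(mo, fa), mother = m, father = f2)
            addind(b, child(mo, fa), mother = m, father = f2)
            addpair(a, b, rel)
        } else if (rel == "second_degree") {
            m <- paste0(tag, "_m")
            a <- paste0(tag, "_a"); b <- paste0(tag, "_b")
            mo <- founder(); f1 <- founder(); f2 <- founder()
            addind(m, mo)
            addind(a, child(mo, f1), mother = m)
            addind(b, child(mo, f2), mother = m)
            addpair(a, b, rel)
        } else if (rel == "third_degree") {
            gm <- founder(); gf <- founder()
            p1 <- child(gm, gf); p2 <- child(gm, gf)
            s1 <- founder(); s2 <- founder()
            a <- paste0(tag, "_a"); b <- paste0(tag, "_b")
            addind(paste0(tag, "_p1"), p1); addind(paste0(tag, "_p2"), p2)
            addind(a, child(p1, s1), mother = paste0(tag, "_p1"))
            addind(b, child(p2, s2), mother = paste0(tag, "_p2"))
            addpair(a, b, rel)
        } else if (rel == "unrelated") {
            a <- paste0(tag, "_a"); b <- paste0(tag, "_b")
            addind(a, founder()); addind(b, founder())
            addpair(a, b, rel)
        } else stop("unknown relationship: ", rel)
    }
    geno <- vapply(inds, function(hp) hp[[1]]$allele + hp[[2]]$allele,
                   integer(ns))
    ibd_df <- if (length(ibd)) do.call(rbind, ibd) else NULL
    true_ibd <- if (!is.null(ibd_df))
        IBDSegments(sample_a = ibd_df$a, sample_b = ibd_df$b,
                    chrom = ibd_df$chrom, start_bp = ibd_df$start_bp,
                    end_bp = ibd_df$end_bp, lod = 100,
                    hap_a = ibd_df$ha, hap_b = ibd_df$hb, map = map)
    else IBDSegments(character(0), character(0), character(0), numeric(0),
                     numeric(0), numeric(0), length_cm = numeric(0))
    list(geno = geno, truth = do.call(rbind, pairs),
         pedigree = do.call(rbind, ped), sites = sites, true_ibd = true_ibd)
}

#' Simulate ROH / UPD fixtures with truth labels
#'
#' Emits HBD segments exactly as planted, plus truth labels computed from
#' the planted lengths: the recent-parental-relatedness flag (total of
#' segments > 20 cM exceeding 50 cM) and the planted UPD chromosome, if
#' any (realized as a single ROH covering \code{upd_fraction} of the
#' chromosome).
#'
#' @param spec list with \code{individuals} — a named list; each element
#'   has \code{segments} (list of \code{c(chrom=, start_cm=, length_cm=)})
#'   and optionally \code{upd_chrom} — plus \code{map} and optional
#'   \code{upd_fraction} (default 0.95).
#' @return list with \code{segments} (HBD \code{IBDSegments}) and
#'   \code{truth} (data.frame id, parental_flag, upd_chrom).
#' @export
simulateROHFixtures <- function(spec) {
    map <- spec$map
    updf <- if (is.null(spec$upd_fraction)) 0.95 else spec$upd_fraction
    cmlen <- chromLengthsCm(map)
    rows <- list(); truth <- list()
    for (id in names(spec$individuals)) {
        ind <- spec$individuals[[id]]
        lens <- numeric(0)
        for (sg in ind$segments) {
            ch <- as.character(sg[["chrom"]])
            st <- as.numeric(sg[["start_cm"]]); le <- as.numeric(sg[["length_cm"]])
            if (st + le > cmlen[[ch]] + 1e-9)
                stop("planted segment exceeds chromosome bounds: ", id)
            rows[[length(rows) + 1L]] <- data.frame(
                id = id, chrom = ch, start_cm = st, end_cm = st + le)
            lens <- c(lens, le)
        }
        upd <- NA_character_
        if (!is.null(ind$upd_chrom)) {
            ch <- ind$upd_chrom
            le <- updf * cmlen[[ch]]
            st <- (cmlen[[ch]] - le) / 2
            rows[[length(rows) + 1L]] <- data.frame(
                id = id, chrom = ch, start_cm = st, end_cm = st + le)
            upd <- ch
            lens <- c(lens, le)
        }
        truth[[length(truth) + 1L]] <- data.frame(
            id = id,
            parental_flag = sum(lens[lens > 20]) > 50,
            upd_chrom = upd)
    }
    d <- do.call(rbind, rows)
    start_bp <- cmToBp(map, d$chrom, d$start_cm)
    end_bp <- pmax(cmToBp(map, d$chrom, d$end_cm), start_bp + 1)
    seg <- IBDSegments(sample_a = d$id, sample_b = d$id, chrom = d$chrom,
                       start_bp = start_bp, end_bp = end_bp, lod = 100,
                       map = map)
    list(segments = seg, truth = do.call(rbind, truth))
}

# brute-force subtree weight for one node: recursion over the edge table,
# independent of the bottom-up pass in accumulateWeights()
.subtreeWeightBrute <- function(atree, placement, node) {
    tree <- atree@tree
    members <- node
    frontier <- node
    while (length(frontier)) {
        kids <- tree$edge[tree$edge[, 1] %in% frontier, 2]
        members <- c(members, kids)
        frontier <- kids
    }
    sum(placement[names(placement) %in% atree@branch_id[members]])
}

#' Simulate placement fixtures with truth haplogroups
#'
#' Builds a small labelled reference tree and a set of placement-weight
#' scenarios (weight concentrated on chosen branches with configurable
#' spill elsewhere). The truth haplogroup of each query is computed by an
#' independent brute-force subtree-sum search for the deepest branch
#' accumulating the threshold.
#'
#' @param spec optional list with \code{newick} (labelled tree string),
#'   \code{queries} (named list; each element a named weight vector over
#'   branch IDs) and \code{threshold} (default 0.99). When NULL, a
#'   default three-clade fixture with tip/clade/spill scenarios is used.
#' @param seed integer seed (used only if spec requests random spill).
#' @return list with \code{tree} (\code{AnnotatedTree}), \code{newick},
#'   \code{placements} and \code{truth} (data.frame query, haplogroup).
#' @export
simulatePlacements <- function(spec = NULL, seed = 1L) {
    set.seed(seed)
    if (is.null(spec)) spec <- list()
    newick <- if (!is.null(spec$newick)) spec$newick else
        "(((A1a:1,A1b:1)A1:1,(A2a:1,A2b:1)A2:1)A:1,(B1:1,B2:1)B:1)R;"
    threshold <- if (is.null(spec$threshold)) 0.99 else spec$threshold
    atree <- annotatedTree(ape::read.tree(text = newick))
    queries <- if (!is.null(spec$queries)) spec$queries else list(
        tip_only = c(A1a = 1),
        clade_split = c(A1a = 0.5, A1b = 0.5),
        spill_out = c(A1a = 0.97, B1 = 0.03),
        small_spill = c(A2a = 0.995, B2 = 0.005))
    truth <- lapply(names(queries), function(q) {
        w <- queries[[q]]; w <- w / sum(w)
        nn <- length(atree@branch_id)
        acc <- vapply(seq_len(nn), function(nd)
            .subtreeWeightBrute(atree, w, nd), 0)
        qual <- which(acc >= threshold - 1e-12)
        pick <- qual[which.max(atree@depth[qual])]
        data.frame(query = q, haplogroup = atree@haplogroup[[pick]])
    })
    list(tree = atree, newick = newick,
         placements = lapply(queries, function(w) w / sum(w)),
         truth = do.call(rbind, truth))
}

#' Write a minimal diploid-GT VCF
#'
#' Plain-text VCFv4.2 with the GT field only; reference allele A,
#' alternate T at every site.
#'
#' @param geno sites x samples dosage matrix.
#' @param sites data.frame with \code{chrom}, \code{pos_bp}.
#' @param path output path.
#' @export
writeVCF <- function(geno, sites, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", colnames(geno)),
                       collapse = "\t")), con)
    gtxt <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow(geno))
    gtxt[is.na(geno)] <- "./."
    body <- paste(sites$chrom, round(sites$pos_bp), ".", "A", "T", ".",
                  "PASS", ".", "GT",
                  apply(gtxt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
    invisible(path)
}
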