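#' Default demonstration genome map
#'
#' A 22-autosome uniform map with human-like genetic lengths (about
#' 3,540 cM total) at a constant 1 cM/Mb, used by the synthetic demo
#' cohort. Real analyses should load the detector's actual genetic map.
#'
#' @return a \code{GenomeMap}.
#' @export
defaultDemoMap <- function() {
    cm <- c(286, 269, 223, 214, 204, 192, 187, 168, 166, 181, 158, 175,
            126, 119, 141, 134, 128, 117, 107, 108, 62, 72)
    uniformGenomeMap(paste0("chr", seq_along(cm)), cm * 1e6, cm)
}

#' Default pipeline configuration
#'
#' Every stage parameter defaults to the printed value of the underlying
#' method where one exists: segment QC at LOD >= 3 and 2 cM (1 cM for ROH
#' and fine-scale clustering), excess-IBD detection on segments > 10 cM
#' with a 3\% trimmed mean and a 10 trimmed-s.d. threshold, the Leiden
#' resolution schedule 0.5 / 0.5 / 3, top-10 sharing networks, a
#' 20,000-site minimum for kinship with the R0 <= 0.02 and
#' 0.4 <= R1 <= 0.6 parent-offspring rule, ROH flagging at > 50 cM in
#' > 20 cM segments, and a 0.99 placement-weight threshold for haplogroup
#' calls.
#'
#' @param seed global integer seed; all stage seeds derive from it.
#' @return nested configuration list for \code{\link{runPipeline}}.
#' @export
defaultRunConfig <- function(seed = 1L) {
    list(
        seed = as.integer(seed),
        simulate = list(
            groups = stats::setNames(rep(15L, 4), paste0("G", 1:4)),
            lambda_in = 6, lambda_out = 0.3, mean_cm = 3, min_cm = 2,
            targets = list(
                T1 = c(G1 = 0.5, G2 = 0.5),
                T2 = c(G1 = 0.2, G2 = 0.8),
                T3 = c(G2 = 0.3, G3 = 0.7),
                T4 = c(G1 = 0.25, G3 = 0.25, G4 = 0.5),
                T5 = c(G3 = 0.9, G4 = 0.1),
                T6 = c(G1 = 1.0)),
            group_age_bp = stats::setNames(
                c(9000, 8000, 6000, 5000), paste0("G", 1:4)),
            age_spread = 400),
        qc = list(min_lod = 3, min_cm = 2, long_cm = 10,
                  trim_fraction = 0.03, z = 10),
        cluster = list(r_start = 0.5, r_step = 0.5, r_max = 3,
                       min_size = 2, max_age_gap = 1000, topk = 10),
        paint = list(se = TRUE),
        kinship = list(
            n_sites = 30000, min_sites = 20000,
            relationships = c(duplicate = 1, parent_offspring = 2,
                              full_sibling = 2, second_degree = 2,
                              third_degree = 1, unrelated = 2)),
        roh = list(long_cm = 20, flag_cm = 50,
                   chrom_fraction = 0.9, elsewhere_cm = 50),
        yhap = list(threshold = 0.99))
}

.writeTSV <- function(d, path) {
    writeLines(paste0("#", paste(names(d), collapse = "\t")), path)
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, append = TRUE)
}

# order-independent checksum-ish fingerprint of the configuration
.configHash <- function(config) {
    s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
    sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 251)) %%
                .Machine$integer.max)
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes, in dependency order: cohort simulation, segment QC (filter,
#' excess-IBD removal), sharing-matrix construction, hierarchical Leiden
#' clustering with spatiotemporal collapsing, leave-one-out painting and
#' supervised ancestry fits of the admixed targets, pedigree-based kinship
#' classification, ROH/UPD flagging, and placement-based haplogroup
#' calling. Writes stage outputs as TSV/BED/JSON under \code{outdir} and a
#' machine-readable run report stamped with the config hash and seed; the
#' run is a pure function of the configuration.
#'
#' @param config configuration list from \code{\link{defaultRunConfig}}
#'   (unknown top-level keys are an error).
#' @param outdir output directory, created if needed.
#' @param map genome map used throughout; default
#'   \code{\link{defaultDemoMap}}.
#' @return the run report, invisibly (also written as
#'   \code{report.json}).
#' @export
runPipeline <- function(config = defaultRunConfig(), outdir = tempfile("run"),
                        map = defaultDemoMap()) {
    known <- c("seed", "simulate", "qc", "cluster", "paint", "kinship",
               "roh", "yhap")
    bad <- setdiff(names(config), known)
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    report <- list(config_hash = .configHash(config), seed = config$seed,
                   stages = list())
    seed <- config$seed

    # --- simulate ---------------------------------------------------------
    simspec <- config$simulate
    simspec$map <- map
    simspec$seed <- seed
    sim <- simulateGroupIBD(simspec)
    set.seed(seed + 1L)
    meta <- sim$truth
    ga <- simspec$group_age_bp
    mu <- ifelse(meta$group == "admixed", mean(ga), ga[meta$group])
    meta$age_bp <- round(mu + stats::runif(nrow(meta), -1, 1) *
                             simspec$age_spread)
    meta$latitude <- round(stats::runif(nrow(meta), 40, 60), 3)
    meta$longitude <- round(stats::runif(nrow(meta), 0, 60), 3)
    meta$region <- meta$group
    meta$contamination_mt <- 0; meta$contamination_nuc <- 0
    meta$autosomal_coverage <- 1; meta$mean_genotype_probability <- 0.99
    writeIBDSegments(sim$segments, file.path(outdir, "ibd_segments.tsv"))
    writeSampleMetadata(meta, file.path(outdir, "metadata.tsv"))
    writeGenomeMap(map, file.path(outdir, "genome_map.tsv"))
    .writeTSV(sim$truth, file.path(outdir, "truth_labels.tsv"))
    report$stages$simulate <- list(n_samples = nrow(meta),
                                   n_segments = length(sim$segments))

    # --- segment QC -------------------------------------------------------
    qc <- config$qc
    filt <- filterSegments(sim$segments, min_lod = qc$min_lod,
                           min_cm = qc$min_cm)
    pile <- computePileup(filt, map, long_cm = qc$long_cm)
    regions <- detectExcessRegions(pile, trim_fraction = qc$trim_fraction,
                                   z = qc$z)
    clean <- suppressMessages(removeExcess(filt, regions))
    bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                      start = GenomicRanges::start(regions) - 1,
                      end = GenomicRanges::end(regions))
    utils::write.table(bed, file.path(outdir, "excess_regions.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    writeIBDSegments(clean, file.path(outdir, "ibd_segments_qc.tsv"))
    report$stages$qc <- list(n_input = length(sim$segments),
                             n_pass_filter = length(filt),
                             n_excess_regions = length(regions),
                             n_after_excess_removal = length(clean))

    # --- sharing matrix + clustering -------------------------------------
    sm <- sharingMatrix(clean, map, samples = sort(meta$id))
    .writeTSV(cbind(id = rownames(sharingValues(sm)),
                    as.data.frame(sharingValues(sm))),
              file.path(outdir, "sharing_matrix.tsv"))
    cl <- config$cluster
    g <- buildNetwork(sm)
    hier <- hierarchicalCluster(g, r_start = cl$r_start, r_step = cl$r_step,
                                r_max = cl$r_max, seed = seed + 2L,
                                min_size = cl$min_size)
    labels <- collapseClusters(hier, meta,
                               rule = list(region_key = "region",
                                           max_age_gap = cl$max_age_gap))
    jsonlite::write_json(hier@root, file.path(outdir, "hierarchy.json"),
                         auto_unbox = TRUE, digits = NA)
    .writeTSV(data.frame(id = names(labels), cluster = unname(labels)),
              file.path(outdir, "cluster_labels.tsv"))
    topk <- topkNetwork(sm, meta,
                        period_breaks = c(0, 5500, 7000, 12000),
                        k = cl$topk)
    .writeTSV(topk, file.path(outdir, "topk_edges.tsv"))
    tl <- withinClusterTimeline(
        sm, labels, stats::setNames(meta$age_bp, meta$id),
        breaks = c(0, 5500, 7000, 12000))
    .writeTSV(tl, file.path(outdir, "within_cluster_timeline.tsv"))
    report$stages$cluster <- list(n_leaves = length(leaves(hier)),
                                  n_final_clusters = length(unique(labels)))

    # --- painting + supervised ancestry ----------------------------------
    members <- meta$id[meta$group != "admixed"]
    donors <- stats::setNames(meta$group[match(members, meta$id)], members)
    targets <- meta$id[meta$group == "admixed"]
    fits <- fitSourceSets(targets, list(all = sort(unique(donors))),
                          clean, donors, map, se = config$paint$se)
    .writeTSV(fits, file.path(outdir, "ancestry_fits.tsv"))
    truemix <- sim$mixtures[targets, sort(unique(donors)), drop = FALSE]
    est <- matrix(fits$proportion, nrow = length(targets), byrow = TRUE,
                  dimnames = list(targets, sort(unique(donors))))
    mae <- mean(abs(est - truemix))
    report$stages$ancestry <- list(n_targets = length(targets),
                                   mean_abs_error_vs_truth = mae)

    # --- kinship ----------------------------------------------------------
    ks <- config$kinship
    ped <- simulatePedigreeCohort(list(relationships = ks$relationships,
                                       n_sites = ks$n_sites, map = map,
                                       seed = seed + 3L))
    kin <- kinshipTable(ped$geno, min_sites = ks$min_sites)
    .writeTSV(kin, file.path(outdir, "kinship_pairs.tsv"))
    focal <- merge(ped$truth, kin, by = c("sample_a", "sample_b"))
    expected <- c(duplicate = "duplicate_MZ",
                  parent_offspring = "parent_offspring",
                  full_sibling = "full_sibling_other_1st",
                  second_degree = "second_degree",
                  third_degree = "third_degree",
                  unrelated = "unrelated")
    acc <- mean(focal$call == expected[focal$relationship])
    report$stages$kinship <- list(n_focal_pairs = nrow(focal),
                                  focal_pair_accuracy = acc)

    # --- ROH / UPD --------------------------------------------------------
    rs <- config$roh
    rohfix <- simulateROHFixtures(list(
        map = map,
        individuals = list(
            flagged = list(segments = list(
                c(chrom = "chr1", start_cm = 10, length_cm = 25),
                c(chrom = "chr3", start_cm = 40, length_cm = 30))),
            borderline = list(segments = list(
                c(chrom = "chr2", start_cm = 5, length_cm = 19))),
            upd_case = list(segments = list(), upd_chrom = "chr2"),
            inbred = list(segments = list(
                c(chrom = "chr1", start_cm = 0, length_cm = 60),
                c(chrom = "chr4", start_cm = 0, length_cm = 55),
                c(chrom = "chr5", start_cm = 10, length_cm = 40))))))
    roh <- summarizeROH(rohfix$segments, map, long_cm = rs$long_cm,
                        flag_cm = rs$flag_cm)
    upd <- detectUPD(roh, map, chrom_fraction = rs$chrom_fraction,
                     elsewhere_cm = rs$elsewhere_cm)
    .writeTSV(roh$summary, file.path(outdir, "roh_summary.tsv"))
    .writeTSV(upd, file.path(outdir, "upd_candidates.tsv"))
    tr <- rohfix$truth[order(rohfix$truth$id), ]
    sm2 <- roh$summary[order(roh$summary$id), ]
    report$stages$roh <- list(
        n_individuals = nrow(sm2),
        n_parental_flagged = sum(sm2$parental_flag),
        flags_match_truth = identical(sm2$parental_flag, tr$parental_flag),
        upd_detected = nrow(upd) == sum(!is.na(tr$upd_chrom)) &&
            all(upd$chrom == tr$upd_chrom[!is.na(tr$upd_chrom)]))

    # --- haplogroup calling ----------------------------------------------
    plc <- simulatePlacements(seed = seed + 4L)
    writeLines(plc$newick, file.path(outdir, "reference_tree.nwk"))
    writePlacements(plc$placements, file.path(outdir, "placements.json"))
    calls <- callHaplogroups(plc$tree, plc$placements,
                             threshold = config$yhap$threshold)
    .writeTSV(calls, file.path(outdir, "haplogroup_calls.tsv"))
    report$stages$yhap <- list(
        n_queries = nrow(calls),
        calls_match_truth = identical(calls$haplogroup,
                                      plc$truth$haplogroup))

    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(report)
}
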