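#' @import methods
#' @importFrom S4Vectors isConstant
NULL

#' GenomeMap: physical-to-genetic coordinate interpolation
#'
#' A genome map holds, per chromosome, a monotone set of (bp, cM) anchor
#' points used for piecewise-linear interpolation between physical and
#' genetic coordinates. All segment lengths in the package are genetic
#' (centimorgan) lengths computed through a \code{GenomeMap}.
#'
#' @slot anchors data.frame with columns \code{chrom}, \code{bp}, \code{cm};
#'   per chromosome the first anchor is the origin and anchors are strictly
#'   increasing in bp with non-decreasing cM.
#'
#' @seealso \code{\link{loadGenomeMap}}, \code{\link{uniformGenomeMap}},
#'   \code{\link{bpToCm}}
#' @exportClass GenomeMap
setClass("GenomeMap", slots = c(anchors = "data.frame"))

setValidity("GenomeMap", function(object) {
    a <- object@anchors
    if (!all(c("chrom", "bp", "cm") %in% names(a)))
        return("anchors must have columns chrom, bp, cm")
    if (nrow(a) == 0L)
        return("empty genome map")
    for (ch in unique(a$chrom)) {
        x <- a[a$chrom == ch, , drop = FALSE]
        if (nrow(x) < 2L)
            return(sprintf("chromosome %s needs at least 2 anchor points", ch))
        if (any(diff(x$bp) <= 0))
            return(sprintf("chromosome %s: bp anchors not strictly increasing", ch))
        if (any(diff(x$cm) < 0))
            return(sprintf("chromosome %s: cM anchors decreasing", ch))
    }
    if (sum(vapply(split(a$cm, a$chrom), function(z) max(z) - min(z), 0)) <= 0)
        return("total genetic length must be > 0")
    TRUE
})

#' IBDSegments: pairwise IBD / HBD segment table
#'
#' Container for genomic segments shared identical-by-descent between pairs
#' of individuals. A row with \code{sample_a == sample_b} is a
#' homozygosity-by-descent (ROH) segment. Pairs are stored in canonical
#' order (lexicographically smaller ID first) and coordinates are 0-based
#' half-open.
#'
#' @slot seg data.frame with columns \code{sample_a}, \code{hap_a},
#'   \code{sample_b}, \code{hap_b}, \code{chrom}, \code{start_bp},
#'   \code{end_bp}, \code{length_cm}, \code{lod}, \code{hbd}.
#'
#' @seealso \code{\link{readIBDSegments}}, \code{\link{filterSegments}}
#' @exportClass IBDSegments
setClass("IBDSegments", slots = c(seg = "data.frame"))

.IBD_COLS <- c("sample_a", "hap_a", "sample_b", "hap_b", "chrom",
               "start_bp", "end_bp", "length_cm", "lod", "hbd")

setValidity("IBDSegments", function(object) {
    s <- object@seg
    if (!all(.IBD_COLS %in% names(s)))
        return(paste("segment table must have columns:",
                     paste(.IBD_COLS, collapse = ", ")))
    if (nrow(s) == 0L) return(TRUE)
    if (any(s$end_bp <= s$start_bp)) return("end_bp must exceed start_bp")
    if (any(s$length_cm < 0)) return("negative length_cm")
    if (any(!is.finite(s$lod))) return("non-finite LOD score")
    if (any(s$sample_a > s$sample_b))
        return("pairs not in canonical order (sample_a <= sample_b)")
    if (any(s$hbd != (s$sample_a == s$sample_b)))
        return("hbd flag inconsistent with sample IDs")
    TRUE
})

#' SharingMatrix: genome fraction shared IBD per pair
#'
#' Symmetric matrix of the fraction of the genome (in cM) shared IBD
#' between pairs of individuals; the edge weights of the clustering
#' network. Diagonal is exactly zero.
#'
#' @slot mat symmetric numeric matrix with sample IDs as dimnames,
#'   values in [0, 1], zero diagonal.
#'
#' @seealso \code{\link{sharingMatrix}}, \code{\link{buildNetwork}}
#' @exportClass SharingMatrix
setClass("SharingMatrix", slots = c(mat = "matrix"))

setValidity("SharingMatrix", function(object) {
    m <- object@mat
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
        return("matrix must have identical row and column sample IDs")
    if (!isSymmetric(unname(m), tol = 1e-12)) return("matrix must be symmetric")
    if (any(diag(m) != 0)) return("diagonal must be exactly 0")
    if (any(m < 0) || any(m > 1)) return("values must lie in [0, 1]")
    TRUE
})

#' ClusterHierarchy: nested community-detection result
#'
#' Rooted tree of iterative Leiden community detection. Each internal node
#' stores its member IDs and the resolution parameter at which it split;
#' leaves store final member sets and a generated path label (for example
#' \code{"C2.1"}).
#'
#' @slot root recursive list with elements \code{members}, \code{resolution}
#'   (NA for leaves), \code{label}, \code{children}.
#' @slot samples character vector of all clustered sample IDs.
#'
#' @seealso \code{\link{hierarchicalCluster}}, \code{\link{leafLabels}}
#' @exportClass ClusterHierarchy
setClass("ClusterHierarchy", slots = c(root = "list", samples = "character"))

setValidity("ClusterHierarchy", function(object) {
    lv <- .collectLeaves(object@root)
    mem <- sort(unlist(lapply(lv, `[[`, "members"), use.names = FALSE))
    if (!identical(mem, sort(object@samples)))
        return("leaves must partition the sample set")
    TRUE
})

#' PileupProfile: per-position long-IBD segment counts
#'
#' Run-length encoded count, along every chromosome, of long IBD segments
#' overlapping each position. Input to excess-IBD region detection.
#'
#' @slot cov \code{RleList} of per-base segment counts (one Rle per
#'   chromosome, covering the chromosome exactly).
#' @slot long_cm minimum (strict) cM length a segment needed to be counted.
#'
#' @seealso \code{\link{computePileup}}, \code{\link{detectExcessRegions}}
#' @exportClass PileupProfile
setClass("PileupProfile",
         slots = c(cov = "ANY", long_cm = "numeric"))

#' AnnotatedTree: reference phylogeny with per-branch haplogroup labels
#'
#' A rooted reference tree in which every branch resolves to a haplogroup
#' label, unlabelled branches inheriting the label of their nearest
#' labelled ancestor.
#'
#' @slot tree an \code{ape} \code{phylo} object (rooted).
#' @slot branch_id character, one ID per node (tips first, ape order).
#' @slot haplogroup character, resolved haplogroup label per node.
#' @slot depth integer, number of edges from the root per node.
#'
#' @seealso \code{\link{annotatedTree}}, \code{\link{callHaplogroup}}
#' @exportClass AnnotatedTree
setClass("AnnotatedTree",
         slots = c(tree = "ANY", branch_id = "character",
                   haplogroup = "character", depth = "integer"))

setValidity("AnnotatedTree", function(object) {
    n <- length(object@branch_id)
    if (length(object@haplogroup) != n || length(object@depth) != n)
        return("branch_id, haplogroup and depth must have one entry per node")
    if (anyDuplicated(object@branch_id)) return("duplicate branch IDs")
    if (any(is.na(object@haplogroup) | object@haplogroup == ""))
        return("every branch must resolve to a haplogroup label")
    TRUE
})
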