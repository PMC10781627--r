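#' Annotate a reference tree with per-branch haplogroup labels
#'
#' Each branch of the rooted reference phylogeny is identified by the name
#' of its child node (tip label, or node label, or \code{node<k>} for
#' unnamed internals) and resolves to a haplogroup label. Branches without
#' their own label inherit the label of the nearest labelled ancestor,
#' matching the sparse SNP annotation of real haplogroup trees.
#'
#' @param tree an \code{ape} \code{phylo} object or path to a Newick file;
#'   must be rooted.
#' @param haplogroups optional named character vector (branch ID ->
#'   haplogroup). When absent, node and tip labels themselves are taken as
#'   haplogroup annotations.
#' @return an \code{\link[=AnnotatedTree-class]{AnnotatedTree}}.
#' @importFrom ape read.tree is.rooted Ntip Nnode
#' @export
annotatedTree <- function(tree, haplogroups = NULL) {
    if (is.character(tree)) tree <- ape::read.tree(tree)
    if (!ape::is.rooted(tree)) stop("reference tree must be rooted")
    ntip <- ape::Ntip(tree); nn <- ntip + ape::Nnode(tree)
    nl <- tree$node.label
    if (is.null(nl)) nl <- rep("", ape::Nnode(tree))
    branch_id <- c(tree$tip.label,
                   ifelse(nl == "" | is.na(nl),
                          paste0("node", seq_len(ape::Nnode(tree)) + ntip), nl))
    parent <- integer(nn); parent[ntip + 1L] <- 0L
    parent[tree$edge[, 2]] <- tree$edge[, 1]
    depth <- integer(nn)
    ord <- ntip + 1L  # preorder from root
    pre <- integer(0)
    stack <- ntip + 1L
    kids <- split(tree$edge[, 2], tree$edge[, 1])
    while (length(stack)) {
        nd <- stack[[1]]; stack <- stack[-1]
        pre <- c(pre, nd)
        ch <- kids[[as.character(nd)]]
        if (!is.null(ch)) {
            depth[ch] <- depth[nd] + 1L
            stack <- c(ch, stack)
        }
    }
    own <- if (is.null(haplogroups)) {
        v <- c(tree$tip.label, ifelse(nl == "" | is.na(nl), NA, nl))
        v
    } else {
        unname(haplogroups[branch_id])
    }
    own[own == ""] <- NA
    hap <- own
    for (nd in pre) {
        if ((is.na(hap[nd])) && parent[nd] > 0L) hap[nd] <- hap[parent[nd]]
    }
    if (any(is.na(hap)))
        stop("root lineage has no haplogroup annotation; cannot resolve")
    new("AnnotatedTree", tree = tree, branch_id = branch_id,
        haplogroup = hap, depth = depth)
}

setMethod("show", "AnnotatedTree", function(object) {
    cat(sprintf("AnnotatedTree: %d tips, %d haplogroup label(s)\n",
                ape::Ntip(object@tree), length(unique(object@haplogroup))))
})

#' Read placement weight sets from jplace-style JSON
#'
#' Expected schema: a top-level \code{placements} array whose elements
#' have a \code{name}, a \code{branches} array of branch IDs and a
#' parallel \code{weights} array. Weights are normalized to sum to 1 on
#' read.
#'
#' @param path path to the JSON file.
#' @return named list of named numeric weight vectors (one per query).
#' @export
readPlacements <- function(path) {
    j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    out <- list()
    for (p in j$placements) {
        w <- as.numeric(unlist(p$weights))
        br <- as.character(unlist(p$branches))
        if (any(w < 0) || sum(w) <= 0) stop("weights not normalizable")
        out[[p$name]] <- stats::setNames(w / sum(w), br)
    }
    out
}

#' @describeIn readPlacements write placements in the same schema.
#' @param placements named list of named weight vectors.
#' @export
writePlacements <- function(placements, path) {
    j <- list(placements = lapply(names(placements), function(nm) {
        list(name = nm,
             branches = as.list(names(placements[[nm]])),
             weights = as.list(unname(placements[[nm]])))
    }))
    jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Accumulate placement weights over subtrees
#'
#' Each branch's accumulated weight is the sum of placement weights on the
#' branch itself and on every branch in its subtree; the root accumulates
#' the full weight (1 for a normalized placement).
#'
#' @param atree an \code{AnnotatedTree}.
#' @param placement named numeric vector, branch ID -> weight.
#' @return named numeric vector of accumulated weights per branch ID.
#' @export
accumulateWeights <- function(atree, placement) {
    unknown <- setdiff(names(placement), atree@branch_id)
    if (length(unknown))
        stop("unknown branch ID(s): ", paste(unknown, collapse = ", "))
    tree <- atree@tree
    nn <- length(atree@branch_id)
    w <- numeric(nn)
    idx <- match(names(placement), atree@branch_id)
    w[idx] <- w[idx] + as.numeric(placement)
    acc <- w
    parent <- integer(nn)
    parent[tree$edge[, 2]] <- tree$edge[, 1]
    for (nd in order(atree@depth, decreasing = TRUE)) {
        if (parent[nd] > 0L) acc[parent[nd]] <- acc[parent[nd]] + acc[nd]
    }
    stats::setNames(acc, atree@branch_id)
}

#' Call a haplogroup from accumulated placement weights
#'
#' Returns the haplogroup of the deepest branch (farthest from the root)
#' whose subtree accumulates at least \code{threshold} of the placement
#' weight. The root always qualifies, so a call always exists; the
#' informative call is the deepest qualifying branch, and equal-depth ties
#' are broken toward the root-ward branch ID ordering. (Read literally, a
#' "most basal" branch accumulating the weight would always be the root;
#' the deepest-qualifying reading is the informative inversion and is the
#' one implemented.)
#'
#' @param atree an \code{AnnotatedTree}.
#' @param placement named weight vector (normalized), or a precomputed
#'   accumulation from \code{\link{accumulateWeights}} via \code{acc}.
#' @param threshold minimum accumulated weight, inclusive; default 0.99.
#' @param acc optional precomputed accumulated weights.
#' @return list with \code{haplogroup}, \code{branch}, \code{weight}.
#' @export
callHaplogroup <- function(atree, placement = NULL, threshold = 0.99,
                           acc = NULL) {
    if (is.null(acc)) acc <- accumulateWeights(atree, placement)
    qual <- which(acc >= threshold - 1e-12)
    d <- atree@depth[qual]
    deepest <- qual[d == max(d)]
    pick <- deepest[order(atree@branch_id[deepest])][1]
    list(haplogroup = atree@haplogroup[[pick]],
         branch = atree@branch_id[[pick]],
         weight = unname(acc[[pick]]))
}

#' Call haplogroups for a set of placed queries
#'
#' @param atree an \code{AnnotatedTree}.
#' @param placements named list from \code{\link{readPlacements}} or
#'   \code{\link{simulatePlacements}}.
#' @param threshold accumulation threshold, default 0.99.
#' @return data.frame (query, haplogroup, branch, weight).
#' @export
callHaplogroups <- function(atree, placements, threshold = 0.99) {
    rows <- lapply(names(placements), function(q) {
        cl <- callHaplogroup(atree, placements[[q]], threshold)
        data.frame(query = q, haplogroup = cl$haplogroup,
                   branch = cl$branch, weight = cl$weight)
    })
    do.call(rbind, rows)
}
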