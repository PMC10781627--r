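#' Build the weighted IBD-sharing network
#'
#' Nodes are samples; an undirected edge joins i and j iff their genome
#' fraction shared IBD is positive, with that fraction as edge weight. No
#' self-loops (the sharing matrix has a zero diagonal).
#'
#' @param x a \code{SharingMatrix}.
#' @return an \code{igraph} weighted undirected graph.
#' @export
buildNetwork <- function(x) {
    stopifnot(is(x, "SharingMatrix"))
    igraph::graph_from_adjacency_matrix(sharingValues(x), mode = "undirected",
                                        weighted = TRUE, diag = FALSE)
}

#' Single-level Leiden community detection
#'
#' One run of the Leiden algorithm at a fixed resolution, using the
#' modularity objective by default (CPM available as an option). The seed
#' fixes the algorithm's internal randomness, so the partition is
#' reproducible; isolated nodes become singleton communities.
#'
#' @param graph weighted undirected \code{igraph} graph.
#' @param resolution resolution parameter, > 0.
#' @param seed integer seed.
#' @param objective \code{"modularity"} (default) or \code{"CPM"}.
#' @param n_iterations Leiden iterations per run, default 5.
#' @return named integer membership vector.
#' @export
detectOnce <- function(graph, resolution, seed = 1L,
                       objective = c("modularity", "CPM"),
                       n_iterations = 5L) {
    objective <- match.arg(objective)
    if (igraph::vcount(graph) == 0L) stop("empty graph")
    stopifnot(resolution > 0)
    set.seed(seed)
    cl <- igraph::cluster_leiden(graph, objective_function = tolower(objective),
                                 resolution = resolution,
                                 weights = igraph::E(graph)$weight,
                                 n_iterations = n_iterations)
    m <- igraph::membership(cl)
    stats::setNames(as.integer(m), igraph::V(graph)$name)
}

#' Iterative hierarchical Leiden clustering
#'
#' Community detection is run at resolution \code{r_start}; if more than
#' one community is found, the network is split into the communities and
#' detection recurses on each subnetwork with the resolution reset to
#' \code{r_start} (each level starts afresh). If only one community is
#' found, the resolution is incremented by \code{r_step} and detection is
#' retried, up to \code{r_max}. A node becomes a leaf when no split occurs
#' at \code{r_max}, or when it has fewer than \code{min_size} members.
#'
#' @param graph weighted undirected \code{igraph} graph with named nodes.
#' @param r_start,r_step,r_max resolution schedule; defaults 0.5 / 0.5 / 3.
#' @param seed integer seed; per-node seeds are derived deterministically.
#' @param min_size minimum splittable node size, default 2.
#' @param reset_resolution if \code{FALSE}, recursion continues from the
#'   parent's split resolution instead of restarting at \code{r_start}.
#' @param objective passed to \code{\link{detectOnce}}.
#' @param split_test \code{"permutation"} (default) gates every candidate
#'   split by a null-model significance test: the split is accepted only
#'   when its plain (resolution-1) weighted modularity exceeds the best
#'   modularity Leiden attains on \code{n_null} degree-preserving rewired,
#'   weight-shuffled null graphs at the same resolution. Raising the
#'   resolution is thereby used to escape the resolution limit (finding
#'   small dense subcommunities), while splits that only exist because of
#'   the resolution penalty — which at r >= 2 will shred even a uniform
#'   clique — are rejected, so homogeneous communities terminate as
#'   leaves. \code{"none"} accepts every multi-community partition.
#' @param n_null null replicates for the permutation gate, default 59.
#' @return a \code{\link[=ClusterHierarchy-class]{ClusterHierarchy}}.
#' @export
hierarchicalCluster <- function(graph, r_start = 0.5, r_step = 0.5, r_max = 3,
                                seed = 1L, min_size = 2L,
                                reset_resolution = TRUE,
                                objective = "modularity",
                                split_test = c("permutation", "none"),
                                n_null = 59L) {
    stopifnot(r_start > 0, r_step > 0, r_start <= r_max)
    split_test <- match.arg(split_test)
    counter <- new.env(); counter$i <- 0L
    splitOK <- function(g, part, r, seed0) {
        if (split_test == "none") return(TRUE)
        w <- igraph::E(g)$weight
        obs <- igraph::modularity(g, part[igraph::V(g)$name], weights = w)
        for (b in seq_len(n_null)) {
            set.seed((seed0 + b) %% .Machine$integer.max)
            gn <- igraph::rewire(
                g, igraph::keeping_degseq(niter = 10 * igraph::ecount(g)))
            igraph::E(gn)$weight <- sample(w)
            nullp <- igraph::cluster_leiden(
                gn, objective_function = "modularity", resolution = r,
                weights = igraph::E(gn)$weight, n_iterations = 5L)
            qn <- igraph::modularity(gn, igraph::membership(nullp),
                                     weights = igraph::E(gn)$weight)
            if (qn >= obs) return(FALSE)
        }
        TRUE
    }
    recurse <- function(g, label, r0) {
        members <- sort(igraph::V(g)$name)
        node <- list(members = members, resolution = NA_real_,
                     label = label, children = list())
        if (length(members) < min_size) return(node)
        r <- r0
        repeat {
            counter$i <- counter$i + 1L
            part <- detectOnce(g, resolution = r,
                               seed = (seed + counter$i) %% .Machine$integer.max,
                               objective = objective)
            if (length(unique(part)) > 1L &&
                !splitOK(g, part, r, seed + 7919L * counter$i))
                part[] <- 1L
            if (length(unique(part)) > 1L) {
                node$resolution <- r
                # order communities by their smallest member ID
                comms <- split(names(part), part)
                comms <- comms[order(vapply(comms, min, ""))]
                node$children <- lapply(seq_along(comms), function(k) {
                    sub <- igraph::induced_subgraph(g, comms[[k]])
                    recurse(sub, paste0(label, ".", k),
                            if (reset_resolution) r_start else r)
                })
                return(node)
            }
            r <- r + r_step
            if (r > r_max + 1e-9) return(node)
        }
    }
    root <- recurse(graph, "C", r_start)
    new("ClusterHierarchy", root = root,
        samples = sort(igraph::V(graph)$name))
}

.collectLeaves <- function(node) {
    if (length(node$children) == 0L) return(list(node))
    do.call(c, lapply(node$children, .collectLeaves))
}

#' @rdname ClusterHierarchy-class
#' @export
setMethod("leaves", "ClusterHierarchy", function(x) .collectLeaves(x@root))

#' @rdname ClusterHierarchy-class
#' @export
setMethod("leafLabels", "ClusterHierarchy", function(x) {
    lv <- leaves(x)
    lab <- rep(vapply(lv, `[[`, "", "label"),
               vapply(lv, function(l) length(l$members), 0L))
    stats::setNames(lab, unlist(lapply(lv, `[[`, "members")))[x@samples]
})

setMethod("show", "ClusterHierarchy", function(object) {
    lv <- leaves(object)
    cat(sprintf("ClusterHierarchy: %d samples in %d leaf cluster(s)\n",
                length(object@samples), length(lv)))
})

#' Collapse hierarchy leaves using spatiotemporal annotations
#'
#' Deterministic, rule-driven simplification of the clustering: sibling
#' leaves (leaves sharing a parent) are merged when they carry the same
#' region annotation and their members' age ranges are separated by at
#' most \code{max_age_gap} years (overlapping ranges have gap 0). Merging
#' is transitive within a sibling set and never crosses parents.
#'
#' @param hierarchy a \code{ClusterHierarchy}.
#' @param samples metadata data.frame with columns \code{id}, \code{age_bp}
#'   and the region column named by the rule.
#' @param rule list with \code{region_key} (metadata column, default
#'   \code{"region"}) and \code{max_age_gap} (years, default 1000).
#' @return named character vector of final labels, one per sample; merged
#'   leaves share the label of their first member leaf.
#' @export
collapseClusters <- function(hierarchy, samples,
                             rule = list(region_key = "region",
                                         max_age_gap = 1000)) {
    stopifnot(rule$max_age_gap >= 0)
    if (!rule$region_key %in% names(samples))
        stop("metadata lacks rule column: ", rule$region_key)
    if (!all(hierarchy@samples %in% samples$id))
        stop("metadata missing for some samples")
    region <- stats::setNames(as.character(samples[[rule$region_key]]),
                              samples$id)
    age <- stats::setNames(samples$age_bp, samples$id)
    labels <- leafLabels(hierarchy)
    walk <- function(node) {
        kids <- node$children
        if (length(kids) == 0L) return(invisible())
        is_leaf <- vapply(kids, function(k) length(k$children) == 0L, TRUE)
        lf <- kids[is_leaf]
        if (length(lf) >= 2L) {
            info <- lapply(lf, function(l) {
                rg <- unique(region[l$members])
                list(label = l$label,
                     region = if (length(rg) == 1L) rg else NA_character_,
                     lo = min(age[l$members]), hi = max(age[l$members]))
            })
            n <- length(info)
            parent_idx <- seq_len(n)  # union-find over sibling leaves
            find <- function(i) { while (parent_idx[i] != i) i <- parent_idx[i]; i }
            for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
                a <- info[[i]]; b <- info[[j]]
                if (is.na(a$region) || is.na(b$region)) next
                gap <- max(0, max(a$lo, b$lo) - min(a$hi, b$hi))
                if (a$region == b$region && gap <= rule$max_age_gap) {
                    ri <- find(i); rj <- find(j)
                    if (ri != rj) parent_idx[max(ri, rj)] <- min(ri, rj)
                }
            }
            for (i in seq_len(n)) {
                r <- find(i)
                if (r != i)
                    labels[labels == info[[i]]$label] <<- info[[r]]$label
            }
        }
        for (k in kids) walk(k)
    }
    walk(hierarchy@root)
    labels
}

#' Top-k sharing network per time period
#'
#' Within each age-bin period, each individual keeps its \code{k}
#' largest-weight sharing partners among individuals of the same period;
#' the union of these directed selections is reported as an undirected
#' edge list. Ties at rank k are broken deterministically by partner ID.
#'
#' @param x a \code{SharingMatrix}.
#' @param samples metadata with \code{id} and \code{age_bp}.
#' @param period_breaks numeric breaks (years BP) partitioning the age
#'   axis, as for \code{cut}.
#' @param k partners kept per individual, default 10.
#' @return data.frame (period, sample_a, sample_b, weight), one row per
#'   undirected edge per period.
#' @export
topkNetwork <- function(x, samples, period_breaks, k = 10) {
    stopifnot(k >= 1)
    m <- sharingValues(x)
    ids <- rownames(m)
    age <- stats::setNames(samples$age_bp, samples$id)[ids]
    per <- cut(age, breaks = period_breaks, include.lowest = TRUE)
    res <- list()
    for (p in levels(per)) {
        sub <- ids[!is.na(per) & per == p]
        if (length(sub) < 2L) next
        mm <- m[sub, sub, drop = FALSE]
        sel <- list()
        for (i in sub) {
            w <- mm[i, ]; w <- w[names(w) != i & w > 0]
            if (length(w) == 0L) next
            o <- order(-w, names(w))
            top <- names(w)[o][seq_len(min(k, length(w)))]
            sel[[i]] <- data.frame(sample_a = pmin(i, top),
                                   sample_b = pmax(i, top),
                                   weight = w[top])
        }
        if (length(sel) == 0L) next
        e <- unique(do.call(rbind, sel))
        e <- e[order(e$sample_a, e$sample_b), , drop = FALSE]
        res[[p]] <- cbind(period = p, e)
    }
    out <- do.call(rbind, res)
    if (is.null(out))
        out <- data.frame(period = character(0), sample_a = character(0),
                          sample_b = character(0), weight = numeric(0))
    rownames(out) <- NULL
    out
}

#' Within-cluster sharing through time
#'
#' Mean pairwise genome-fraction sharing among same-cluster individuals,
#' per cluster and per time bin, with the number of contributing pairs.
#' Bins with fewer than two cluster members yield \code{NA} (no pairs).
#'
#' @param x a \code{SharingMatrix}.
#' @param labels named cluster label per sample.
#' @param ages named age (years BP) per sample.
#' @param breaks numeric bin breaks on the age axis.
#' @return data.frame (cluster, bin, n_pairs, mean_sharing).
#' @export
withinClusterTimeline <- function(x, labels, ages, breaks) {
    m <- sharingValues(x)
    ids <- rownames(m)
    bin <- cut(ages[ids], breaks = breaks, include.lowest = TRUE)
    out <- list()
    for (cl in sort(unique(labels[ids]))) {
        for (b in levels(bin)) {
            sub <- ids[labels[ids] == cl & !is.na(bin) & bin == b]
            np <- length(sub) * (length(sub) - 1) / 2
            mu <- if (np > 0) {
                mm <- m[sub, sub, drop = FALSE]
                mean(mm[upper.tri(mm)])
            } else NA_real_
            out[[length(out) + 1L]] <- data.frame(
                cluster = cl, bin = b, n_pairs = np, mean_sharing = mu)
        }
    }
    do.call(rbind, out)
}
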