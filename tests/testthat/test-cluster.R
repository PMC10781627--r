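.smat <- function(m, ids = NULL) {
    if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(m)))
    dimnames(m) <- list(ids, ids)
    diag(m) <- 0
    new("SharingMatrix", mat = m)
}

# block matrix: k cliques of size s with within weight win, between wout
.blockMatrix <- function(k, s, win = 1, wout = 0) {
    m <- matrix(wout, k * s, k * s)
    for (i in seq_len(k)) {
        idx <- ((i - 1) * s + 1):(i * s)
        m[idx, idx] <- win
    }
    m
}

test_that("the sharing network has one weighted edge per nonzero pair", {
    m0 <- matrix(0, 4, 4)
    expect_equal(igraph::ecount(buildNetwork(.smat(m0))), 0)
    m <- matrix(0, 3, 3)
    m[1, 2] <- m[2, 1] <- 0.1; m[1, 3] <- m[3, 1] <- 0.05
    g <- buildNetwork(.smat(m))
    expect_equal(igraph::ecount(g), 2)
    expect_setequal(igraph::E(g)$weight, c(0.1, 0.05))
    set.seed(9)
    r <- matrix(runif(64) * (runif(64) < 0.4), 8, 8)
    r <- (r + t(r)) / 2
    expect_equal(igraph::ecount(buildNetwork(.smat(r))),
                 sum(r[upper.tri(r)] > 0))
})

test_that("Leiden respects disconnected components", {
    g <- buildNetwork(.smat(.blockMatrix(2, 10)))
    # exact recovery at the schedule's starting resolution
    p <- detectOnce(g, 0.5, seed = 4)
    expect_equal(length(unique(p)), 2)
    expect_equal(length(unique(p[1:10])), 1)
    expect_equal(length(unique(p[11:20])), 1)
    # at any resolution, no community ever spans two components
    comp <- rep(1:2, each = 10)
    for (r in c(0.5, 1, 3)) {
        p <- detectOnce(g, r, seed = 4)
        expect_true(all(vapply(split(comp, p), function(z)
            length(unique(z)) == 1L, TRUE)))
    }
    expect_identical(detectOnce(g, 0.5, seed = 4), detectOnce(g, 0.5, seed = 4))
    expect_error(detectOnce(igraph::make_empty_graph(0), 0.5), "empty")
})

test_that("a homogeneous clique stays one leaf through the full schedule", {
    g <- buildNetwork(.smat(matrix(1, 10, 10)))
    h <- hierarchicalCluster(g, seed = 2)
    expect_equal(length(leaves(h)), 1)
    expect_true(is.na(h@root$resolution))  # never split, r reached the cap
    h2 <- hierarchicalCluster(g, seed = 2)
    expect_identical(h@root, h2@root)      # determinism contract
})

test_that("nested structure yields a two-level hierarchy with sub-clique leaves", {
    w <- matrix(0.0005, 20, 20)
    blk <- function(i) ((i - 1) * 5 + 1):(i * 5)
    for (i in 1:4) w[blk(i), blk(i)] <- 1
    for (p in list(c(1, 2), c(3, 4))) {
        w[blk(p[1]), blk(p[2])] <- 0.2
        w[blk(p[2]), blk(p[1])] <- 0.2
    }
    h <- hierarchicalCluster(buildNetwork(.smat(w)), seed = 3)
    lab <- leafLabels(h)
    expect_equal(length(leaves(h)), 4)
    truth <- rep(1:4, each = 5)
    expect_equal(length(unique(tapply(truth, lab, length))), 1)
    expect_equal(h@root$resolution, 0.5)
    # leaves partition the sample set (validity invariant, checked live)
    expect_setequal(names(lab), sprintf("s%02d", 1:20))
})

test_that("collapse merges sibling leaves by region and age overlap only", {
    w <- .blockMatrix(3, 4, win = 1, wout = 0.001)
    ids <- sprintf("s%02d", 1:12)
    h <- hierarchicalCluster(buildNetwork(.smat(w, ids)), seed = 5)
    expect_equal(length(leaves(h)), 3)
    meta <- data.frame(id = ids,
                       region = rep(c("north", "north", "south"), each = 4),
                       age_bp = rep(c(5000, 5400, 5200), each = 4))
    lab <- collapseClusters(h, meta)
    # the two north leaves overlap in age (gap 0 < 1000) -> merged
    expect_equal(length(unique(lab)), 2)
    expect_equal(length(unique(lab[ids[1:8]])), 1)
    # different regions never merge even with identical ages
    meta2 <- meta; meta2$region <- rep(c("a", "b", "c"), each = 4)
    expect_equal(length(unique(collapseClusters(h, meta2))), 3)
    # age gap beyond the rule blocks the merge
    meta3 <- meta; meta3$age_bp <- rep(c(5000, 6500, 5200), each = 4)
    expect_equal(length(unique(collapseClusters(h, meta3))), 3)
    expect_error(collapseClusters(h, meta[, c("id", "age_bp")]), "rule column")
})

test_that("chained age overlaps merge transitively within a sibling set", {
    w <- .blockMatrix(3, 4, win = 1, wout = 0.001)
    ids <- sprintf("s%02d", 1:12)
    h <- hierarchicalCluster(buildNetwork(.smat(w, ids)), seed = 5)
    # leaf ages 5000 / 5900 / 6800: adjacent gaps 900 <= 1000, ends 1800 apart
    meta <- data.frame(id = ids, region = "r",
                       age_bp = rep(c(5000, 5900, 6800), each = 4))
    lab <- collapseClusters(h, meta)
    expect_equal(length(unique(lab)), 1)
})

test_that("top-k edges keep exactly k partners within each period", {
    set.seed(21)
    n <- 16
    m <- matrix(runif(n * n, 0.01, 1), n, n); m <- (m + t(m)) / 2
    sm <- .smat(m)
    m <- sharingValues(sm)
    ids <- rownames(m)
    samples <- data.frame(id = ids, age_bp = 5000)
    e <- topkNetwork(sm, samples, period_breaks = c(0, 1e4), k = 10)
    deg <- table(c(e$sample_a, e$sample_b))
    expect_true(all(deg >= 10))            # everyone picked their 10
    for (i in ids) {                       # every pick is in i's own top 10
        w <- m[i, setdiff(ids, i)]
        chosen <- union(e$sample_b[e$sample_a == i], e$sample_a[e$sample_b == i])
        expect_true(all(sort(w[chosen], decreasing = TRUE)[1:10] >=
                        sort(w, decreasing = TRUE)[10]))
    }
    # fewer partners than k -> all kept
    m3 <- matrix(0.2, 4, 4)
    e3 <- topkNetwork(.smat(m3), data.frame(id = sprintf("s%02d", 1:4),
                                            age_bp = 1), c(0, 10), k = 10)
    expect_equal(nrow(e3), 6)
    # tie at rank k broken by partner ID, deterministically
    mt <- matrix(0.5, 3, 3)
    et <- topkNetwork(.smat(mt), data.frame(id = sprintf("s%02d", 1:3),
                                            age_bp = 1), c(0, 10), k = 1)
    expect_identical(et, topkNetwork(.smat(mt),
                                     data.frame(id = sprintf("s%02d", 1:3),
                                                age_bp = 1), c(0, 10), k = 1))
    expect_true(all(et$sample_a < et$sample_b))
})

test_that("within-cluster timeline reports means and missing cells", {
    m <- matrix(0.2, 6, 6)
    sm <- .smat(m)
    ids <- rownames(sharingValues(sm))
    labels <- stats::setNames(rep("c1", 6), ids)
    ages <- stats::setNames(c(1000, 1000, 1000, 3000, 3000, 5000), ids)
    tl <- withinClusterTimeline(sm, labels, ages, breaks = c(0, 2000, 4000, 6000))
    expect_equal(tl$mean_sharing[1:2], c(0.2, 0.2))   # flat matrix -> flat
    expect_true(is.na(tl$mean_sharing[3]))            # single member, no pairs
    expect_equal(tl$n_pairs, c(3, 1, 0))
})
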