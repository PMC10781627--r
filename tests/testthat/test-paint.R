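# two-chromosome map and a small donor cohort used across painting tests
.paintMap <- function() uniformGenomeMap(c("chr1", "chr2"), c(1e8, 1e8),
                                         c(100, 100))

.segs <- function(rows, map) {
    IBDSegments(sample_a = rows$a, sample_b = rows$b, chrom = rows$chrom,
                start_bp = rows$start, end_bp = rows$end, lod = 10, map = map)
}

test_that("painting profiles normalize hand-enumerated group totals", {
    map <- .paintMap()
    rows <- data.frame(
        a = c("T", "T", "T"), b = c("A1", "A2", "B1"),
        chrom = c("chr1", "chr1", "chr2"),
        start = c(0, 1e7, 0), end = c(1e7, 3e7, 7e7))
    donors <- c(A1 = "A", A2 = "A", B1 = "B")
    pr <- paintingProfile("T", .segs(rows, map), donors, map)
    # group A: 10 + 20 = 30 cM; group B: 70 cM
    expect_equal(unname(pr$profile), c(0.3, 0.7))
    expect_equal(sum(pr$profile), 1)
    expect_equal(unname(pr$totals_cm["A", ]), c(30, 0))
    expect_equal(unname(pr$totals_cm["B", ]), c(0, 70))
})

test_that("leave-one-out: a target's own sharing never enters its profile", {
    map <- .paintMap()
    rows <- data.frame(a = c("A1", "A1"), b = c("A2", "B1"),
                       chrom = "chr1", start = c(0, 0), end = c(2e7, 1e7))
    donors <- c(A1 = "A", A2 = "A", B1 = "B")
    pr <- paintingProfile("A1", .segs(rows, map), donors, map)
    # A1 paints against A2 (its own group, allowed: only self is excluded)
    # and B1; its own ID is never a donor
    expect_equal(unname(pr$profile), c(2 / 3, 1 / 3))
    # a sample sharing only with itself has no profile
    hbd <- .segs(data.frame(a = "X", b = "X", chrom = "chr1",
                            start = 0, end = 1e7), map)
    expect_error(paintingProfile("X", hbd, c(X = "A", A1 = "A"), map),
                 "no profile")
})

test_that("source profiles are member means with unit column sums", {
    map <- .paintMap()
    rows <- data.frame(
        a = c("A1", "A1", "A2", "A2", "B1"),
        b = c("A2", "B1", "B1", "B2", "B2"),
        chrom = "chr1",
        start = c(0, 0, 0, 0, 0),
        end = c(1e7, 2e7, 3e7, 1e7, 2e7))
    donors <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
    x <- .segs(rows, map)
    S <- sourceProfiles(c("A", "B"), x, donors, map)
    expect_equal(colSums(S), c(A = 1, B = 1))
    pA1 <- paintingProfile("A1", x, donors, map)$profile
    pA2 <- paintingProfile("A2", x, donors, map)$profile
    expect_equal(unname(S[, "A"]), unname((pA1 + pA2) / 2))
    expect_error(sourceProfiles("Z", x, donors, map), "unknown source")
})

test_that("simplex NNLS solves exact and orthogonal cases", {
    S <- diag(3)
    colnames(S) <- c("a", "b", "c")
    f <- simplexNNLS(S, c(0, 1, 0))
    expect_equal(unname(f$w), c(0, 1, 0))
    expect_equal(f$residual, 0)
    f2 <- simplexNNLS(S[, 1:2], c(0.3, 0.7, 0))
    expect_equal(unname(f2$w), c(0.3, 0.7))
    expect_equal(f2$residual, 0, tolerance = 1e-12)
    expect_error(simplexNNLS(cbind(S[, 1:2], 0), c(1, 0, 0)), "degenerate")
})

test_that("constrained fit matches the simplex grid-search oracle", {
    set.seed(101)
    for (k in 2:3) for (rep in 1:5) {
        # diagonally dominant sources: distinct, well-conditioned columns
        S <- matrix(stats::runif(5 * k, 0, 0.2), 5, k)
        S[seq_len(k), seq_len(k)] <- S[seq_len(k), seq_len(k), drop = FALSE] +
            diag(k)
        S <- sweep(S, 2, colSums(S), "/")
        colnames(S) <- paste0("s", seq_len(k))
        w0 <- stats::rexp(k); w0 <- w0 / sum(w0)
        p <- as.numeric(S %*% w0) + stats::rnorm(5, 0, 0.02)
        p <- pmax(p, 0); p <- p / sum(p)
        exact <- simplexNNLS(S, p)
        grid <- gridSearchFit(S, p)
        expect_lt(max(abs(exact$w - grid$w)), 0.0100001)
        expect_lte(exact$residual, grid$residual + 1e-12)
    }
})

test_that("jackknife SE is zero for identical blocks and reduces to the
           unweighted formula for equal-length blocks", {
    map <- .paintMap()  # two equal 100 cM chromosomes
    donors <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
    # identical sharing pattern on both chromosomes -> all loo fits equal
    tt <- matrix(c(30, 30, 70, 70), 2, 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("chr1", "chr2")))
    withinA <- matrix(c(50, 50, 0, 0), 2, 2, byrow = TRUE,
                      dimnames = dimnames(tt))
    withinB <- matrix(c(0, 0, 50, 50), 2, 2, byrow = TRUE,
                      dimnames = dimnames(tt))
    mts <- list(A1 = withinA, A2 = withinA, B1 = withinB, B2 = withinB)
    jk <- jackknifeSE(tt, c("A", "B"), NULL, donors, map,
                      member_totals = mts)
    expect_equal(unname(jk$se), c(0, 0))
    expect_equal(unname(jk$proportions), c(0.3, 0.7))
    # unequal per-chromosome sharing, equal block lengths: compare against
    # the classic delete-one jackknife computed by hand from the loo fits
    tt2 <- matrix(c(20, 40, 80, 60), 2, 2, byrow = TRUE,
                  dimnames = dimnames(tt))
    jk2 <- jackknifeSE(tt2, c("A", "B"), NULL, donors, map,
                       member_totals = mts)
    loo <- jk2$loo
    g <- 2
    se_hand <- sqrt((g - 1) / g * colSums(sweep(loo, 2, colMeans(loo))^2))
    expect_equal(unname(jk2$se), unname(se_hand))
    expect_error(jackknifeSE(tt[, 1, drop = FALSE], "A", NULL, donors,
                             uniformGenomeMap("chr1", 1e8, 100),
                             member_totals = mts), "2 chromosomes")
})

test_that("source-set driver returns one fit per target per set with
           non-increasing residual for nested sets", {
    map <- .paintMap()
    set.seed(33)
    # three well-separated groups, one admixed target
    rows <- list()
    gmem <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B", C1 = "C", C2 = "C")
    for (g in c("A", "B", "C")) {
        mem <- names(gmem)[gmem == g]
        rows[[g]] <- data.frame(a = mem[1], b = mem[2], chrom = "chr1",
                                start = 0, end = 5e7)
    }
    rows$t <- data.frame(a = c("T", "T"), b = c("A1", "B1"),
                         chrom = "chr2", start = c(0, 5e7),
                         end = c(3e7, 9e7))
    x <- .segs(do.call(rbind, rows), map)
    fits <- fitSourceSets("T", list(ab = c("A", "B"), abc = c("A", "B", "C")),
                          x, gmem, map, se = FALSE)
    expect_equal(nrow(fits), 5)
    r_ab <- fits$residual[fits$set == "ab"][1]
    r_abc <- fits$residual[fits$set == "abc"][1]
    expect_lte(r_abc, r_ab + 1e-12)
    expect_error(fitSourceSets("T", list(bad = "Z"), x, gmem, map),
                 "unknown group")
})
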