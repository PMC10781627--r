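test_that("segment filters apply the printed operators at the boundaries", {
    map <- tinyMap(1e8, 100)
    x <- IBDSegments(sample_a = rep("a", 5), sample_b = rep("b", 5),
                     chrom = "chr1",
                     start_bp = c(0, 0, 0, 0, 0) + (0:4) * 1e7,
                     end_bp = c(2e6, 1.9e6, 1e7, 5e6, 1.5e6) + (0:4) * 1e7,
                     lod = c(3.0, 3.5, 2.9, 10, 2.99), map = map)
    kept <- segmentTable(filterSegments(x))
    # (LOD 3.0, 2.0 cM) kept inclusively; LOD 2.9 dropped despite 10 cM
    expect_equal(nrow(kept), 2)
    expect_equal(kept$lod, c(3.0, 10))
    # clustering / roh modes relax the length threshold to 1 cM
    expect_equal(length(filterSegments(x, mode = "clustering")), 3)
    expect_error(filterSegments(x, min_lod = -1), "non-negative")
})

test_that("pileup counts match a brute-force per-base oracle", {
    map <- toyMap()
    # staircase of overlapping long segments
    d <- data.frame(chrom = "chr1",
                    start_bp = c(1000, 2000, 3000, 4000),
                    end_bp = c(4000, 5500, 7000, 8000))
    x <- IBDSegments(sample_a = letters[1:4], sample_b = LETTERS[1:4],
                     chrom = d$chrom, start_bp = d$start_bp,
                     end_bp = d$end_bp, lod = 10, map = map)
    pile <- computePileup(x, map, long_cm = 10)
    expect_equal(as.integer(pile@cov[["chr1"]]),
                 brutePileup(d, 1e4, map, 10))
    # nothing above the length class -> all-zero profile
    y <- IBDSegments("a", "b", "chr1", 0, 900, lod = 10, map = map)
    expect_equal(sum(as.integer(computePileup(y, map)@cov[["chr1"]])), 0)
})

test_that("excess regions: constant profiles are clean, spikes are flagged exactly", {
    map <- toyMap(1e5)  # 1,000 cM so a > 10 cM spike can cover < 3% of mass
    # count 1 everywhere: trimmed sd 0, strict inequality -> nothing flagged
    x <- IBDSegments("a", "b", "chr1", 0, 1e5, lod = 10, map = map)
    expect_equal(length(detectExcessRegions(computePileup(x, map))), 0)
    # baseline of 1 plus a 100-deep, 11 cM spike on 1.1% of positions
    all <- IBDSegments(
        sample_a = c("a", sprintf("c%03d", 1:99)),
        sample_b = c("b", sprintf("d%03d", 1:99)),
        chrom = "chr1", start_bp = c(0, rep(50000, 99)),
        end_bp = c(1e5, rep(51100, 99)), lod = 10, map = map)
    reg <- detectExcessRegions(computePileup(all, map))
    expect_equal(length(reg), 1)
    expect_equal(GenomicRanges::start(reg), 50001)
    expect_equal(GenomicRanges::end(reg), 51100)
    expect_equal(S4Vectors::mcols(reg)$peak_count, 100)
    # two separated spikes stay two maximal runs
    two <- IBDSegments(
        sample_a = c("a", sprintf("c%03d", 1:99), sprintf("e%03d", 1:99)),
        sample_b = c("b", sprintf("d%03d", 1:99), sprintf("f%03d", 1:99)),
        chrom = "chr1", start_bp = c(0, rep(20000, 99), rep(80000, 99)),
        end_bp = c(1e5, rep(21100, 99), rep(81100, 99)), lod = 10, map = map)
    expect_equal(length(detectExcessRegions(computePileup(two, map))), 2)
})

test_that("excess detection is invariant to segment input order", {
    map <- toyMap()
    set.seed(11)
    n <- 40
    st <- sample(0:8000, n); en <- st + sample(500:2000, n, TRUE)
    x <- IBDSegments(sample_a = sample(letters, n, TRUE),
                     sample_b = sample(LETTERS, n, TRUE),
                     chrom = "chr1", start_bp = st, end_bp = pmin(en, 1e4),
                     lod = 10, map = map)
    r1 <- detectExcessRegions(computePileup(x, map))
    perm <- sample(n)
    r2 <- detectExcessRegions(computePileup(x[perm], map))
    expect_equal(GenomicRanges::start(r1), GenomicRanges::start(r2))
    expect_equal(GenomicRanges::end(r1), GenomicRanges::end(r2))
})

test_that("segments overlapping excess regions are removed by any-overlap", {
    map <- toyMap()
    reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3001, 5000))
    x <- IBDSegments(sample_a = paste0("p", 1:4), sample_b = paste0("q", 1:4),
                     chrom = "chr1",
                     start_bp = c(3500, 1000, 5000, 0),
                     end_bp = c(4000, 3000, 6000, 3001),
                     lod = 10, map = map)
    kept <- suppressMessages(removeExcess(x, reg))
    s <- segmentTable(kept)
    # region covers 0-based [3000, 5000): [3500,4000) is inside (removed),
    # [1000,3000) and [5000,6000) abut without a shared base (kept),
    # [0,3001) shares base 3000 (removed)
    expect_equal(nrow(s), 2)
    expect_setequal(s$sample_a, c("p2", "p3"))
    expect_equal(length(suppressMessages(removeExcess(kept, reg))), 2)
})

test_that("hand-enumerated mixed fixture: 4 of 10 overlap and are dropped", {
    map <- toyMap()
    st <- c(100, 1200, 2500, 3100, 4700, 5600, 6500, 7200, 8100, 9000)
    en <- st + 400
    x <- IBDSegments(sample_a = paste0("p", 1:10), sample_b = paste0("q", 1:10),
                     chrom = "chr1", start_bp = st, end_bp = en, lod = 10,
                     map = map)
    # overlaps segments 3 and 4 (first region), 6, 8; last region falls in a gap
    reg <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
        start = c(2600, 5700, 7300, 9500), end = c(3200, 5800, 7400, 9600)))
    kept <- suppressMessages(removeExcess(x, reg))
    expect_equal(length(kept), 6)
})

test_that("sharing matrix is a union-merged cM fraction", {
    map <- uniformGenomeMap(c("chr1", "chr2"), c(2e9, 1.5e9), c(2000, 1500))
    # one 35 cM segment on a 3,500 cM genome -> 0.01
    x <- mkseg("a", "b", 0, 35e6, map)
    m <- sharingValues(sharingMatrix(x, map, c("a", "b", "c")))
    expect_equal(m["a", "b"], 0.01)
    expect_equal(m["b", "a"], 0.01)
    expect_equal(m["a", "c"], 0)
    expect_equal(diag(m), c(a = 0, b = 0, c = 0))
    # overlapping same-pair segments 0-10 and 5-15 cM merge to 15, not 20
    y <- IBDSegments(sample_a = c("a", "a"), sample_b = c("b", "b"),
                     chrom = "chr1", start_bp = c(0, 5e6),
                     end_bp = c(10e6, 15e6), lod = 10, map = map)
    expect_equal(sharingValues(sharingMatrix(y, map, c("a", "b")))["a", "b"],
                 15 / 3500)
    # whole-genome duplicate clips to 1
    z <- IBDSegments(sample_a = c("a", "a"), sample_b = c("b", "b"),
                     chrom = c("chr1", "chr2"), start_bp = c(0, 0),
                     end_bp = c(2e9, 1.5e9), lod = 10, map = map)
    expect_equal(sharingValues(sharingMatrix(z, map, c("a", "b")))["a", "b"], 1)
    # unknown sample is an error
    expect_error(sharingMatrix(x, map, c("a", "x")), "absent")
})

test_that("sharing is invariant to splitting a segment into abutting halves", {
    map <- tinyMap(1e8, 100)
    whole <- mkseg("a", "b", 1e7, 3e7, map)
    halves <- IBDSegments(sample_a = c("a", "a"), sample_b = c("b", "b"),
                          chrom = "chr1", start_bp = c(1e7, 2e7),
                          end_bp = c(2e7, 3e7), lod = 10, map = map)
    expect_equal(sharingValues(sharingMatrix(whole, map, c("a", "b"))),
                 sharingValues(sharingMatrix(halves, map, c("a", "b"))))
})

test_that("the full QC chain is idempotent", {
    map <- toyMap()
    set.seed(3)
    n <- 60
    st <- sample(0:8000, n); en <- pmin(st + sample(300:2500, n, TRUE), 1e4)
    x <- IBDSegments(sample_a = sample(paste0("s", 1:8), n, TRUE),
                     sample_b = sample(paste0("t", 1:8), n, TRUE),
                     chrom = "chr1", start_bp = st, end_bp = en,
                     lod = runif(n, 2, 12), map = map)
    chain <- function(x) {
        f <- filterSegments(x)
        reg <- detectExcessRegions(computePileup(f, map))
        suppressMessages(removeExcess(f, reg))
    }
    once <- chain(x)
    twice <- chain(once)
    expect_equal(segmentTable(twice), segmentTable(once))
})
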