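test_that("joint genotype counts match a brute-force site loop", {
    set.seed(17)
    gi <- sample(c(0:2, NA), 1000, TRUE, prob = c(0.3, 0.3, 0.3, 0.1))
    gj <- sample(c(0:2, NA), 1000, TRUE, prob = c(0.3, 0.3, 0.3, 0.1))
    jc <- jointCounts(gi, gj)
    brute <- matrix(0, 3, 3)
    for (s in seq_len(1000)) {
        if (!is.na(gi[s]) && !is.na(gj[s]))
            brute[gi[s] + 1, gj[s] + 1] <- brute[gi[s] + 1, gj[s] + 1] + 1
    }
    expect_equal(unname(jc$counts), brute)
    expect_equal(jc$n, sum(brute))
    # masked and missing edge cases
    expect_equal(jointCounts(gi, gj, rep(FALSE, 1000))$n, 0)
    expect_equal(jointCounts(rep(NA_integer_, 10), rep(1L, 10))$n, 0)
    expect_error(jointCounts(1:3, 1:4), "length")
})

test_that("identical genomes give KING = 0.5 and R0 = 0 in closed form", {
    g <- c(rep(1L, 50), rep(0L, 25), rep(2L, 25))
    est <- kinshipEstimators(jointCounts(g, g))
    expect_identical(est$king, 0.5)
    expect_identical(est$R0, 0)
    expect_equal(est$n_sites, 100)
    # 50 double-het + 50 concordant hom: N[1][1] = 50, off-diagonal empty
    jc <- jointCounts(g, g)
    expect_equal(jc$counts["1", "1"], 50)
    expect_equal(sum(jc$counts) - sum(diag(jc$counts)), 0)
})

test_that("estimators are symmetric under swapping the pair", {
    set.seed(23)
    for (rep in 1:5) {
        gi <- sample(0:2, 2000, TRUE)
        gj <- sample(0:2, 2000, TRUE)
        a <- kinshipEstimators(jointCounts(gi, gj))
        b <- kinshipEstimators(jointCounts(gj, gi))
        expect_equal(a$R0, b$R0)
        expect_equal(a$R1, b$R1)
        expect_equal(a$king, b$king)
    }
})

test_that("classification applies the site minimum and the PO rule literally", {
    mk <- function(king, R0 = 0.001, R1 = 0.5, n = 1e5)
        list(R0 = R0, R1 = R1, king = king, n_sites = n)
    expect_equal(classifyPair(mk(0.25, n = 15000)), "excluded")
    expect_equal(classifyPair(mk(0.25, n = 20000)), "parent_offspring")
    expect_equal(classifyPair(mk(0.25, R0 = 0.05)), "full_sibling_other_1st")
    expect_equal(classifyPair(mk(0.25, R1 = 0.61)), "full_sibling_other_1st")
    expect_equal(classifyPair(mk(0.25, R0 = 0.02, R1 = 0.4)),
                 "parent_offspring")  # inclusive boundaries as printed
    expect_equal(classifyPair(mk(0.4)), "duplicate_MZ")
    # the duplicate boundary is strict: exactly 2^(-3/2) is first degree
    expect_equal(classifyPair(mk(2^-1.5 + 1e-9, R0 = 0.1)), "duplicate_MZ")
    expect_equal(classifyPair(mk(2^-1.5, R0 = 0.1)), "full_sibling_other_1st")
    expect_equal(classifyPair(mk(0.1, R0 = 0.3, R1 = 0.2)), "second_degree")
    expect_equal(classifyPair(mk(0.05, R0 = 0.4, R1 = 0.1)), "third_degree")
    expect_equal(classifyPair(mk(0.0)), "unrelated")
    expect_equal(classifyPair(list(R0 = NA, R1 = NA, king = NA, n_sites = 1e5)),
                 "excluded")
})

test_that("the lower-coverage member of each close pair is flagged", {
    kin <- data.frame(sample_a = c("a", "c", "e"),
                      sample_b = c("b", "d", "f"),
                      call = c("parent_offspring", "second_degree", "unrelated"))
    cov <- c(a = 2, b = 0.5, c = 0.1, d = 1, e = 5, f = 0.01)
    fl <- flagLowerQualityRelative(kin, cov)
    expect_equal(fl, data.frame(id = c("b", "c"), flag = c("1d_rel", "2d_rel")))
    # a chain of three mutual first-degree samples flags the two
    # lower-coverage members
    kin3 <- data.frame(sample_a = c("x", "x", "y"),
                       sample_b = c("y", "z", "z"),
                       call = "full_sibling_other_1st")
    fl3 <- flagLowerQualityRelative(kin3, c(x = 3, y = 1, z = 2))
    expect_setequal(fl3$id, c("y", "z"))
    # coverage tie broken by flagging the larger sample ID
    flt <- flagLowerQualityRelative(
        data.frame(sample_a = "a", sample_b = "b", call = "parent_offspring"),
        c(a = 1, b = 1))
    expect_equal(flt$id, "b")
})

test_that("relative flags flow into the sample filter verdicts", {
    map <- tinyMap(1e8, 100)
    ped <- simulatePedigreeCohort(list(
        relationships = c(parent_offspring = 1), n_sites = 25000,
        map = map, seed = 5, record_ibd = FALSE))
    kin <- kinshipTable(ped$geno)
    ids <- colnames(ped$geno)
    cov <- stats::setNames(seq_along(ids) / 2, ids)
    fl <- flagLowerQualityRelative(kin, cov)
    meta <- data.frame(id = ids, contamination_mt = 0, contamination_nuc = 0,
                       autosomal_coverage = cov,
                       mean_genotype_probability = 0.99)
    res <- applySampleFilters(meta, relative_flags = fl)
    expect_true(all(res$id[!res$pass] %in% fl$id))
    expect_equal(sum(!res$pass), length(unique(fl$id)))
})

test_that("VCF and TSV genotype matrices read back identically", {
    map <- tinyMap(1e8, 100)
    ped <- simulatePedigreeCohort(list(
        relationships = c(unrelated = 1), n_sites = 500, map = map,
        seed = 9, record_ibd = FALSE))
    f <- tempfile(fileext = ".vcf")
    writeVCF(ped$geno, ped$sites, f)
    g2 <- readGenotypeMatrix(f)
    expect_equal(unname(g2), unname(ped$geno))
    expect_equal(colnames(g2), colnames(ped$geno))
    # cross-check the VCF dialect against an independent parser
    v <- suppressWarnings(vcfR::read.vcfR(f, verbose = FALSE))
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- matrix(c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)[gt], nrow(gt))
    expect_equal(unname(dos), unname(ped$geno))
})
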