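test_that("Fisher test handles symmetry, null tables and zero margins", {
    expect_equal(fisherAlleleTest(10, 10, 10, 10), 1.0)
    # row-swap symmetry
    set.seed(14)
    for (i in 1:20) {
        t4 <- sample(0:40, 4, replace = TRUE) + c(1, 1, 1, 1)
        expect_equal(fisherAlleleTest(t4[1], t4[2], t4[3], t4[4]),
                     fisherAlleleTest(t4[3], t4[4], t4[1], t4[2]))
    }
    expect_equal(fisherOracle(50, 0, 25, 25),
                 fisherAlleleTest(50, 0, 25, 25))
    expect_warning(p0 <- fisherAlleleTest(0, 0, 5, 5), "zero margin")
    expect_equal(p0, 1)
})

test_that("Fisher p-values match fisher.test on random tables", {
    set.seed(15)
    for (i in 1:200) {
        a <- sample(0:60, 1); b <- sample(0:60, 1)
        c_ <- sample(0:30, 1); d <- sample(0:30, 1)
        if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0)
            next
        expect_equal(fisherAlleleTest(a, b, c_, d),
                     fisher.test(matrix(c(a, c_, b, d), 2))$p.value,
                     tolerance = 1e-10)
    }
})

test_that("BH adjustment matches the literal step-up procedure", {
    p <- c(0.001, 0.004, 0.0075, 0.5)
    q <- bhFdr(p)
    expect_equal(q, bhOracle(p))
    expect_equal(sum(q <= 0.01), 3L)   # k = 3 largest with p(k) <= 0.01 k/4
    expect_equal(bhFdr(rep(1, 10)), rep(1, 10))
    expect_equal(bhFdr(0.037), 0.037)  # single p: q = p
    set.seed(16)
    for (i in 1:10) {
        p <- runif(sample(2:100, 1))^2
        expect_equal(bhFdr(p), bhOracle(p))
    }
    expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH rejections contain the Bonferroni rejections", {
    set.seed(17)
    p <- runif(500)^3
    alpha <- 0.05
    bonf <- which(p <= alpha / length(p))
    bh <- which(bhFdr(p) <= alpha)
    expect_true(all(bonf %in% bh))
})

test_that("planted differentiated SNPs are recovered and alpha=0 is empty", {
    set.seed(18)
    n <- 2000
    planted <- sample(n, 60)
    roles <- c(rep("domestic", 4), "wild")
    domFreq <- rep(0.35, n); wildFreq <- rep(0.35, n)
    domFreq[planted] <- 0.02; wildFreq[planted] <- 0.5
    minor <- cbind(matrix(rbinom(4 * n, 38, domFreq), n, 4),
                   rbinom(n, 30, wildFreq))
    major <- cbind(matrix(38L, n, 4), 30L) - minor
    pc <- makeSnpCounts("chr1", seq_len(n) * 50L, major, minor, roles)
    snps <- callCandidates(pc)
    res <- findSignificant(snps, alpha = 0.01)
    sigPos <- start(rowRanges(res$significant))
    sens <- mean((planted * 50L) %in% sigPos)
    expect_gt(sens, 0.9)
    expect_equal(nrow(findSignificant(snps, alpha = 0)$significant), 0L)
})

test_that("per-strain mode unions single-strain differentiation", {
    roles <- c(rep("domestic", 4), "wild")
    # strain 2 differentiated, the other three identical to wild
    minor <- matrix(c(60L, 0L, 60L, 60L, 60L), 1)
    major <- matrix(c(90L, 150L, 90L, 90L, 90L), 1)
    pc <- makeSnpCounts("chr1", 100L, major, minor, roles)
    snps <- callCandidates(pc)
    pooled <- findSignificant(snps, alpha = 1e-4)
    perStrain <- findSignificant(snps, alpha = 1e-4, mode = "per-strain")
    expect_equal(nrow(pooled$significant), 0L)   # dilution hides it
    expect_equal(nrow(perStrain$significant), 1L)
})

test_that("null panels reject at most alpha plus binomial noise", {
    cfg <- simulationConfig(genome = list(chr1 = 1.2e6), seed = 22,
                            driftC = 0, sweeps = GRanges())
    snps <- callCandidates(simulateCounts(simulateFrequencies(cfg), cfg))
    flt <- applyFilter(snps, filterCriteria(30, 300, 5))$snps
    res <- findSignificant(flt, alpha = 0.01)
    frac <- nrow(res$significant) / nrow(flt)
    bound <- 0.01 + 3 * sqrt(0.01 * 0.99 / nrow(flt))
    expect_lte(frac, bound)
})

test_that("location categories partition SNPs with an inclusive 100-bp rim", {
    # coding interval [201, 300] 1-based; SNP exactly 100 bp away at 101
    feat <- GRanges("chr1", IRanges(201, 300))
    mcols(feat) <- S4Vectors::DataFrame(feature_id = "cds1", is_coding = TRUE)
    pos <- c(250L, 101L, 100L, 400L, 401L)
    major <- matrix(30L, 5, 1); minor <- matrix(10L, 5, 1)
    snps <- callCandidates(makeSnpCounts("chr1", sort(pos), major, minor,
                                         roles = "wild"))
    got <- categorizeLocation(snps, feat)
    cat <- as.character(rowData(got)$category)
    names(cat) <- start(rowRanges(got))
    expect_equal(unname(cat[c("250", "101", "100", "400", "401")]),
                 c("coding", "near_coding", "non_coding",
                   "near_coding", "non_coding"))
    expect_equal(sum(table(rowData(got)$category)), nrow(got))
})

test_that("location categories ignore feature order and strand", {
    set.seed(23)
    feat <- GRanges("chr1", IRanges(sort(sample.int(9000, 10)) * 10L,
                                    width = 500),
                    strand = sample(c("+", "-", "*"), 10, TRUE))
    mcols(feat) <- S4Vectors::DataFrame(feature_id = paste0("f", 1:10),
                                        is_coding = TRUE)
    n <- 200
    snps <- callCandidates(makeSnpCounts(
        "chr1", sort(sample.int(1e5, n)), matrix(30L, n, 1),
        matrix(10L, n, 1), roles = "wild"))
    a <- categorizeLocation(snps, feat)
    b <- categorizeLocation(snps, rev(feat))
    unstranded <- feat
    strand(unstranded) <- "*"
    c_ <- categorizeLocation(snps, unstranded)
    expect_equal(rowData(a)$category, rowData(b)$category)
    expect_equal(rowData(a)$category, rowData(c_)$category)
})

test_that("chromosome bins count and conserve assigned SNPs", {
    major <- matrix(30L, 3, 1); minor <- matrix(10L, 3, 1)
    snps <- callCandidates(makeSnpCounts(
        "chr1", c(10L, 150000L, 250000L), major, minor, roles = "wild"))
    bins <- chromosomeBins(snps)
    expect_equal(bins$count, c(2L, 1L))
    expect_equal(attr(bins, "unassigned"), 0L)
    expect_equal(sum(bins$count), nrow(snps))

    onlyChr2 <- chromosomeBins(snps, chroms = "chr2")
    expect_equal(sum(onlyChr2$count), 0L)
    expect_equal(attr(onlyChr2, "unassigned"), 3L)
})
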