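.windowSnps <- function(major, minor, pos = seq_len(nrow(major)) * 100L,
                        roles = c("domestic", "wild")) {
    callCandidates(makeSnpCounts("chr1", pos, major, minor, roles))
}

test_that("window Hp reproduces the pooled-heterozygosity formula", {
    # 5 SNPs, domestic major = minor = 10 -> Hp = 0.5 (maximal)
    major <- cbind(rep(10L, 5), rep(10L, 5))
    minor <- cbind(rep(10L, 5), rep(10L, 5))
    w <- windowHp(.windowSnps(major, minor))
    expect_length(w, 1L)
    expect_equal(mcols(w)$sumMaj, 50L)
    expect_equal(mcols(w)$sumMin, 50L)
    expect_equal(mcols(w)$hp, 0.5)

    # majors 30 each, minors 2,1,2,0,0 -> Hp = 2*150*5/155^2
    major <- cbind(rep(30L, 5), rep(30L, 5))
    minor <- cbind(c(2L, 1L, 2L, 0L, 0L), rep(5L, 5))
    w <- windowHp(.windowSnps(major, minor))
    expect_equal(mcols(w)$hp, 2 * 150 * 5 / 155^2, tolerance = 1e-12)
    expect_equal(round(mcols(w)$hpTransformed, 2), 4.00)
})

test_that("windows below the SNP floor are omitted", {
    major <- cbind(rep(30L, 4), rep(30L, 4))
    minor <- cbind(rep(3L, 4), rep(10L, 4))
    expect_length(windowHp(.windowSnps(major, minor)), 0L)
    expect_length(windowHp(.windowSnps(major, minor), minSnps = 4), 1L)
    expect_error(windowHp(.windowSnps(major, minor), windowSize = 0),
                 "positive")
})

test_that("Hp orientation is recomputed within the scanned pools", {
    # catalogue-wide major is A (wild-dominated), but domestic favours G:
    # in-scope reorientation must keep Hp <= 0.5 regardless
    major <- cbind(rep(2L, 5), rep(200L, 5))   # domestic, wild for allele A
    minor <- cbind(rep(40L, 5), rep(100L, 5))  # allele G
    w <- windowHp(.windowSnps(major, minor))
    expect_equal(mcols(w)$sumMaj, 200L)   # pmax(2, 40) summed
    expect_equal(mcols(w)$sumMin, 10L)
    expect_true(all(mcols(w)$hp <= 0.5))
})

test_that("Hp is symmetric, maximal iff balanced and zero iff fixed", {
    hpOf <- function(SM, Sm) 2 * SM * Sm / (SM + Sm)^2
    set.seed(31)
    for (i in 1:50) {
        SM <- sample(0:200, 1); Sm <- sample(0:200, 1)
        if (SM + Sm == 0) next
        expect_equal(hpOf(SM, Sm), hpOf(Sm, SM))
        expect_lte(hpOf(SM, Sm), 0.5)
    }
    expect_equal(hpOf(77, 77), 0.5)
    expect_equal(hpOf(77, 0), 0)
})

test_that("an all-major SNP drags window Hp down, a balanced one up", {
    base <- list(major = cbind(rep(30L, 6), rep(30L, 6)),
                 minor = cbind(c(5L, 4L, 6L, 5L, 4L, 0L), rep(5L, 6)))
    hpWith <- function(lastMinor) {
        m <- base$minor; m[6, 1] <- lastMinor
        maj <- base$major
        # keep the site a candidate via the wild pool's minor reads
        mcols(windowHp(.windowSnps(maj, m)))$hp
    }
    hp5 <- mcols(windowHp(.windowSnps(base$major[-6, ], base$minor[-6, ])))$hp
    expect_lt(hpWith(0L), hp5)      # fixed SNP added: toward sweep signal
    expect_gt(hpWith(30L), hp5)     # balanced SNP added: toward 0.5
})

test_that("non-overlapping tiling assigns each SNP to at most one window", {
    cfg <- simulationConfig(genome = list(chr1 = 6e5), seed = 13)
    snps <- callCandidates(simulateCounts(simulateFrequencies(cfg), cfg))
    w <- windowHp(snps, minSnps = 1)
    expect_lte(sum(mcols(w)$nSnps), nrow(snps))
    expect_equal(anyDuplicated(start(w)), 0L)
    # overlapping scan at half-window step sees each SNP at most twice
    w2 <- windowHp(snps, step = 10000, minSnps = 1)
    expect_lte(sum(mcols(w2)$nSnps), 2L * nrow(snps))
})

test_that("transformed scores invert Hp and cap at zero heterozygosity", {
    expect_equal(transformHp(0.5), 1.0)
    expect_equal(round(transformHp(0.012), 2), 6.38)
    expect_equal(transformHp(0), 7)
    expect_equal(transformHp(0, cap = 9), 9)
    expect_error(transformHp(0.6), "\\[0, 0.5\\]")
    expect_error(transformHp(-0.1), "\\[0, 0.5\\]")
})

.mkWindows <- function(chrom, starts, scores, width = 20000) {
    gr <- GRanges(chrom, IRanges(starts, width = width))
    mcols(gr) <- S4Vectors::DataFrame(
        nSnps = 9L, sumMaj = 100L, sumMin = 2L,
        hp = 2^(-scores), hpTransformed = scores)
    gr
}

test_that("sweep calling is threshold-inclusive and merges neighbours", {
    w <- .mkWindows("chr1", c(1, 20001, 40001), c(1.2, 4.0, 3.9))
    reg <- callSweeps(w)
    expect_length(reg, 1L)   # inclusive at exactly 4
    expect_equal(start(reg), 20001L)

    w2 <- .mkWindows("chr1", c(1, 20001), c(4.5, 5.5))
    reg2 <- callSweeps(w2)
    expect_length(reg2, 1L)  # boundary-sharing windows merge
    expect_equal(width(reg2), 40000L)

    # ranking: capped (hp = 0) windows first, then by peak score
    w3 <- .mkWindows(c("chr1", "chr2"), c(1, 1), c(4.2, 5.0))
    mcols(w3)$hp[2] <- 0
    mcols(w3)$hpTransformed[2] <- 7
    reg3 <- callSweeps(w3)
    expect_equal(as.character(seqnames(reg3)), c("chr2", "chr1"))
})

test_that("genes attach to sweeps by any overlap", {
    reg <- GRanges("chr1", IRanges(40001, 80000))
    mcols(reg) <- S4Vectors::DataFrame(
        minHp = 0, maxTransformed = 7,
        windowIds = IRanges::IntegerList(list(1L)))
    feat <- GRanges("chr1", IRanges(c(50000, 80000, 90000), width = 3000))
    mcols(feat) <- S4Vectors::DataFrame(
        feature_id = c("inside", "edge1bp", "outside"),
        is_coding = FALSE)
    ann <- annotateSweeps(reg, feat)
    expect_equal(sort(unlist(mcols(ann)$genes)), c("edge1bp", "inside"))

    desert <- GenomicRanges::shift(reg, 2e6)
    expect_length(unlist(mcols(annotateSweeps(desert, feat))$genes), 0L)
})

test_that("planted sweeps are recovered exactly on the default genome", {
    cfg <- simulationConfig(seed = 101)
    truth <- simulateFrequencies(cfg)
    res <- runSweepPipeline(simulateCounts(truth, cfg))
    hits <- findOverlaps(truth@sweepRegions, res$sweeps)
    expect_equal(length(unique(S4Vectors::queryHits(hits))), 3L)
    # no called window farther than one window from a planted region
    slack <- truth@sweepRegions + 20000L
    expect_equal(sum(countOverlaps(res$sweeps, slack) == 0L), 0L)
})
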