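test_that("candidate calling orients alleles and applies the minor floor", {
    counts <- list(matrix(c(100, 0, 6, 0,    # A=100, G=6 -> candidate
                            100, 0, 1, 0,    # minor count 1 < 2 -> dropped
                            50, 0, 0, 50,    # A/T tie -> major A by alphabet
                            90, 5, 4, 0),    # credible third allele -> dropped
                          ncol = 4, byrow = TRUE,
                          dimnames = list(NULL, c("A", "C", "G", "T"))))
    pc <- makeCounts("chr1", c(10L, 20L, 30L, 40L), counts, roles = "wild")
    snps <- callCandidates(pc)
    expect_equal(nrow(snps), 2L)
    expect_equal(majorAllele(snps), c("A", "A"))
    expect_equal(minorAllele(snps), c("G", "T"))
    expect_equal(maf(snps), c(6 / 106, 0.5))
})

test_that("depth and minor-count criteria remove the right candidates", {
    major <- matrix(c(21L, 96L, 200L), ncol = 1)
    minor <- matrix(c(4L, 4L, 8L), ncol = 1)
    pc <- makeSnpCounts("chr1", c(10L, 20L, 30L), major, minor, roles = "wild")
    cand <- callCandidates(pc)
    expect_equal(nrow(cand), 3L)
    strict <- applyFilter(cand, filterCriteria(30, 300, 5))
    expect_equal(start(rowRanges(strict$snps)), 30L)   # depth 25 and minor 4 removed
    relaxed <- applyFilter(cand, filterCriteria(30, 300, 3))
    expect_equal(start(rowRanges(relaxed$snps)), c(20L, 30L))
})

test_that("quantile max-depth specs resolve to the stated percentile", {
    set.seed(21)
    depths <- rpois(5000, 150)
    major <- matrix(pmax(depths - 10L, 0L), ncol = 1)
    minor <- matrix(rep(10L, 5000), ncol = 1)
    pc <- makeSnpCounts("chr1", seq_len(5000), major, minor, roles = "wild")
    cand <- callCandidates(pc)
    st <- applyFilter(cand, filterCriteria(20, "top2%", 2),
                      depthDistribution = totalDepth(cand))$stats
    expect_equal(st$resolvedMaxDepth,
                 unname(quantile(totalDepth(cand), 0.98)))
})

test_that("percent reads included is depth-weighted coverage retained", {
    major <- matrix(c(20L, 90L, 400L), ncol = 1)
    minor <- matrix(c(5L, 10L, 20L), ncol = 1)
    pc <- makeSnpCounts("chr1", c(10L, 20L, 30L), major, minor, roles = "wild")
    cand <- callCandidates(pc)
    st <- applyFilter(cand, filterCriteria(30, 300, 5))$stats
    expect_equal(st$pctReadsIncluded, 100 * 100 / (25 + 100 + 420))
})

test_that("tightening any single factor never increases the SNP count", {
    cfg <- simulationConfig(genome = list(chr1 = 4e5), seed = 12)
    pc <- simulateCounts(simulateFrequencies(cfg), cfg)
    cand <- callCandidates(pc)
    depths <- siteDepth(pc)
    grid <- criteriaGrid(cand, list(
        filterCriteria(20, "top2%", 2), filterCriteria(30, "top2%", 2),
        filterCriteria(30, 300, 3), filterCriteria(30, 150, 3),
        filterCriteria(30, 300, 5), filterCriteria(30, 150, 5),
        filterCriteria(50, 300, 5), filterCriteria(50, 150, 5)),
        depthDistribution = depths)
    tighter <- function(i, j)   # all three resolved factors at least as tight
        grid$minDepth[j] >= grid$minDepth[i] &&
        grid$resolvedMaxDepth[j] <= grid$resolvedMaxDepth[i] &&
        grid$minMinor[j] >= grid$minMinor[i]
    for (i in 1:8) for (j in 1:8)
        if (i != j && tighter(i, j))
            expect_lte(grid$nSnps[j], grid$nSnps[i])
    # a permissive set keeps every candidate
    permissive <- criteriaGrid(cand, list(filterCriteria(1, 1e9, 2)))
    expect_equal(permissive$nSnps, nrow(cand))
})

test_that("stricter criteria admit strictly fewer error-driven false SNPs", {
    cfg <- simulationConfig(genome = list(chr1 = 1e6), seed = 19,
                            backgroundDensity = 1 / 100)
    truth <- simulateFrequencies(cfg)
    pc <- simulateCounts(truth, cfg)
    cand <- callCandidates(pc)
    truePos <- paste0(seqnames(truth@sites), ":", start(truth@sites))
    isFP <- function(s) {
        got <- paste0(seqnames(rowRanges(s)), ":", start(rowRanges(s)))
        sum(!got %in% truePos)
    }
    depths <- siteDepth(pc)
    relaxed <- applyFilter(cand, filterCriteria(20, "top2%", 2), depths)$snps
    strict <- applyFilter(cand, filterCriteria(30, 300, 5), depths)$snps
    expect_gt(isFP(relaxed), 0)
    expect_lt(isFP(strict), isFP(relaxed))
})

test_that("MAF spectrum bins conserve totals and isolate exact 0.5", {
    major <- matrix(c(96L, 93L, 85L, 50L), ncol = 1)
    minor <- matrix(c(4L, 7L, 15L, 50L), ncol = 1)
    pc <- makeSnpCounts("chr1", c(1L, 2L, 3L, 4L) * 10L, major, minor,
                        roles = "wild")
    snps <- callCandidates(pc)
    sp <- mafSpectrum(snps)
    expect_equal(sp$count, c(1L, 1L, 1L, 0L, 0L, 1L))
    expect_equal(attr(sp, "exactHalf"), 1L)
    expect_equal(sum(sp$count), nrow(snps))
})

test_that("every emitted SNP has MAF in [0, 0.5]", {
    cfg <- simulationConfig(genome = list(chr1 = 3e5), seed = 4)
    snps <- callCandidates(simulateCounts(simulateFrequencies(cfg), cfg))
    expect_true(all(maf(snps) >= 0 & maf(snps) <= 0.5))
    expect_true(all(rowData(snps)$majorReads >= rowData(snps)$minorReads))
})

test_that("strain classification separates common, specific and other", {
    roles <- c(rep("domestic", 4), "wild")
    # site 1: polymorphic everywhere -> common
    # site 2: polymorphic only in pool 2, others deep monomorphic -> specific
    # site 3: polymorphic in pool 2, pool 4 depth 10 -> other
    major <- matrix(c(30L, 30L, 30L, 30L, 30L,
                      40L, 30L, 40L, 40L, 40L,
                      40L, 30L, 40L, 10L, 40L), ncol = 5, byrow = TRUE)
    minor <- matrix(c(10L, 10L, 10L, 10L, 10L,
                      0L, 10L, 0L, 0L, 0L,
                      0L, 10L, 0L, 0L, 0L), ncol = 5, byrow = TRUE)
    pc <- makeSnpCounts("chr1", c(100L, 200L, 300L), major, minor, roles)
    cls <- classifyStrainSnps(pc, filterCriteria(30, 300, 5))
    expect_equal(start(cls$common), 100L)
    expect_equal(start(cls$strainSpecific[["pool2"]]), 200L)
    expect_equal(sum(lengths(cls$strainSpecific[-2])), 0L)
    expect_equal(start(cls$other), 300L)
})

test_that("strain-specific sets are disjoint from each other and from common", {
    cfg <- simulationConfig(genome = list(chr1 = 3e5), seed = 9,
                            driftModel = "bottleneck", driftC = 0.2)
    pc <- simulateCounts(simulateFrequencies(cfg), cfg)
    cls <- classifyStrainSnps(pc, filterCriteria(20, 100, 3))
    key <- function(gr) paste0(seqnames(gr), ":", start(gr))
    specific <- lapply(cls$strainSpecific, key)
    allSpec <- unlist(specific)
    expect_equal(anyDuplicated(allSpec), 0L)
    expect_length(intersect(allSpec, key(cls$common)), 0L)
    expect_length(intersect(allSpec, key(cls$other)), 0L)
})

test_that("per-strain summary percentages round to one decimal", {
    df <- strainSnpSummary(c(a = 7100489, b = 4898477), c(66487, 143126))
    expect_equal(df$percentage, c(0.9, 2.9))
})
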