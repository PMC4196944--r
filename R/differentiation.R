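#' Two-tailed Fisher's exact test on allele read counts
#'
#' Exact hypergeometric test of the 2x2 table
#' \code{[[domMajor, domMinor], [wildMajor, wildMinor]]}, vectorised over
#' SNPs. Two-sidedness follows the classical convention: the p-value sums
#' the probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table (up to a
#' relative tolerance of 1e-7, as in \code{\link[stats]{fisher.test}}).
#' Tables with a zero margin carry no information and return p = 1 with a
#' warning.
#'
#' Conditioning on the margins, the domestic major count follows a
#' hypergeometric distribution; the implementation enumerates its support
#' with \code{\link[stats]{dhyper}}, flattened across SNPs, so a catalogue
#' of 1e5 SNPs tests in well under a second.
#'
#' @param domMajor,domMinor,wildMajor,wildMinor non-negative integer read
#'   counts, recycled to a common length.
#' @return numeric vector of two-tailed p-values.
#' @examples
#' fisherAlleleTest(10, 10, 10, 10)            # identical proportions: 1
#' fisherAlleleTest(50, 0, 25, 25)
#' stats::fisher.test(matrix(c(50, 25, 0, 25), 2))$p.value
#' @export
fisherAlleleTest <- function(domMajor, domMinor, wildMajor, wildMinor) {
    n <- max(length(domMajor), length(domMinor),
             length(wildMajor), length(wildMinor))
    a <- rep_len(as.numeric(domMajor), n)
    b <- rep_len(as.numeric(domMinor), n)
    c_ <- rep_len(as.numeric(wildMajor), n)
    d <- rep_len(as.numeric(wildMinor), n)
    if (any(c(a, b, c_, d) < 0)) stop("read counts must be non-negative")
    r1 <- a + b          # domestic depth
    r2 <- c_ + d         # wild depth
    k <- a + c_          # major-allele column margin
    N <- r1 + r2
    p <- rep(1, n)
    zero <- r1 == 0 | r2 == 0 | k == 0 | (N - k) == 0
    if (any(zero))
        warning(sum(zero), " table(s) with a zero margin: p set to 1")
    live <- which(!zero)
    if (length(live)) {
        lo <- pmax(0, k[live] - r2[live])
        hi <- pmin(r1[live], k[live])
        len <- hi - lo + 1
        idx <- rep(live, len)
        xs <- sequence(len) - 1 + rep(lo, len)
        probs <- stats::dhyper(xs, k[idx], N[idx] - k[idx], r1[idx])
        pobs <- stats::dhyper(a[live], k[live], N[live] - k[live], r1[live])
        keep <- probs <= pobs[match(idx, live)] * (1 + 1e-7)
        sums <- rowsum(probs * keep, idx)
        p[as.integer(rownames(sums))] <- pmin(sums[, 1L], 1)
    }
    p
}

#' False discovery rate adjustment
#'
#' Benjamini--Hochberg step-up adjusted p-values (or the
#' Benjamini--Yekutieli variant valid under arbitrary dependence), with
#' monotonicity enforced and input order preserved.
#'
#' @param p numeric p-values in \eqn{[0, 1]}.
#' @param method \code{"BH"} (default) or \code{"BY"}.
#' @return numeric q-values in input order.
#' @examples
#' bhFdr(c(0.001, 0.004, 0.0075, 0.5))
#' @export
bhFdr <- function(p, method = c("BH", "BY")) {
    method <- match.arg(method)
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = method)
}

#' Identify SNPs differentiated between domestic and wild pools
#'
#' Tests every SNP's allele read counts between the domestic pools
#' (summed into one margin by default, reflecting a single test per SNP)
#' and the wild pool, adjusts the p-values for multiple testing, and
#' returns the SNPs whose q-value is at most \code{alpha}. In
#' \code{"per-strain"} mode each domestic pool is tested against the wild
#' pool separately and a SNP is significant when any strain's q-value
#' passes (its smallest q is reported).
#'
#' @param snps a \linkS4class{SnpCatalog} with pool roles in its colData.
#' @param alpha FDR significance level (default 0.01).
#' @param mode \code{"pooled"} (default) or \code{"per-strain"}.
#' @param fdrMethod passed to \code{\link{bhFdr}}.
#' @return list with \code{significant} (the \linkS4class{SnpCatalog} subset
#'   with rowData columns \code{p}, \code{q} added) and \code{all} (the
#'   full catalogue with the same columns).
#' @examples
#' cfg <- simulationConfig(genome = list(chr1 = 5e4), seed = 3)
#' snps <- callCandidates(simulateCounts(simulateFrequencies(cfg), cfg))
#' res <- findSignificant(snps, alpha = 0.01)
#' nrow(res$significant)
#' @export
findSignificant <- function(snps, alpha = 0.01,
                            mode = c("pooled", "per-strain"),
                            fdrMethod = "BH") {
    mode <- match.arg(mode)
    if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
    dom <- which(poolRoles(snps) == "domestic")
    wld <- wildPool(snps)
    if (length(dom) == 0L) stop("no pool is configured with the 'domestic' role")
    wMaj <- rowSums(majorCounts(snps)[, wld, drop = FALSE])
    wMin <- rowSums(minorCounts(snps)[, wld, drop = FALSE])
    if (mode == "pooled") {
        dMaj <- rowSums(majorCounts(snps)[, dom, drop = FALSE])
        dMin <- rowSums(minorCounts(snps)[, dom, drop = FALSE])
        p <- fisherAlleleTest(dMaj, dMin, wMaj, wMin)
        q <- bhFdr(p, fdrMethod)
    } else {
        qs <- vapply(dom, function(pool) {
            pv <- fisherAlleleTest(majorCounts(snps)[, pool],
                                   minorCounts(snps)[, pool], wMaj, wMin)
            bhFdr(pv, fdrMethod)
        }, numeric(nrow(snps)))
        ps <- vapply(dom, function(pool)
            fisherAlleleTest(majorCounts(snps)[, pool],
                             minorCounts(snps)[, pool], wMaj, wMin),
            numeric(nrow(snps)))
        if (nrow(snps) == 1L) { qs <- matrix(qs, 1L); ps <- matrix(ps, 1L) }
        p <- apply(ps, 1L, min)
        q <- apply(qs, 1L, min)
    }
    rowData(snps)$p <- p
    rowData(snps)$q <- q
    list(significant = snps[q <= alpha, ], all = snps)
}

#' Categorise SNPs by genomic location
#'
#' A SNP is \code{coding} when it lies inside a coding interval,
#' \code{near_coding} when it lies outside but within \code{nearBp} of a
#' coding interval boundary (inclusive: a SNP exactly \code{nearBp} away
#' is near-coding), and \code{non_coding} otherwise. Feature order and
#' strand never affect the result, and the three category counts always
#' partition the input.
#'
#' @param snps a \linkS4class{SnpCatalog} (typically the significant subset).
#' @param features a \link[GenomicRanges]{GRanges} from
#'   \code{\link{readAnnotation}}; only intervals with
#'   \code{is_coding = TRUE} are used.
#' @param nearBp the near-coding distance in bp (default 100).
#' @return \code{snps} with a rowData factor column \code{category}.
#' @export
categorizeLocation <- function(snps, features, nearBp = 100) {
    features <- .asFeatures(features)
    coding <- features[mcols(features)$is_coding]
    pos <- rowRanges(snps)
    inCoding <- countOverlaps(pos, coding, ignore.strand = TRUE) > 0L
    near <- countOverlaps(pos, coding + nearBp, ignore.strand = TRUE) > 0L &
        !inCoding
    cat <- rep("non_coding", nrow(snps))
    cat[near] <- "near_coding"
    cat[inCoding] <- "coding"
    rowData(snps)$category <-
        factor(cat, levels = c("coding", "near_coding", "non_coding"))
    snps
}

#' Count SNPs in consecutive chromosome bins
#'
#' @param snps a \linkS4class{SnpCatalog}.
#' @param binSize bin width in bp (default 200 kb).
#' @param chroms chromosomes considered "assigned"; SNPs on other
#'   sequences (e.g. unanchored scaffolds) are excluded from the bins and
#'   reported in the \code{"unassigned"} attribute. Default: all observed.
#' @return data.frame with \code{chrom}, \code{binStart} (1-based),
#'   \code{binEnd}, \code{count}, covering each chromosome contiguously
#'   from its first bin through the last SNP-bearing bin; attribute
#'   \code{"unassigned"} holds the excluded SNP count.
#' @examples
#' # bins [1, 200000] and [200001, 400000]
#' @export
chromosomeBins <- function(snps, binSize = 200000, chroms = NULL) {
    chrom <- as.character(seqnames(rowRanges(snps)))
    pos <- start(rowRanges(snps))
    if (is.null(chroms)) chroms <- unique(chrom)
    assigned <- chrom %in% chroms
    out <- lapply(chroms, function(ch) {
        p <- pos[chrom == ch]
        if (length(p) == 0L)
            return(data.frame(chrom = character(), binStart = integer(),
                              binEnd = integer(), count = integer()))
        idx <- (p - 1L) %/% binSize            # 0-based bin index
        nbin <- max(idx) + 1L
        cnt <- tabulate(idx + 1L, nbins = nbin)
        data.frame(chrom = ch,
                   binStart = as.integer(binSize * (seq_len(nbin) - 1L) + 1L),
                   binEnd = as.integer(binSize * seq_len(nbin)),
                   count = cnt)
    })
    res <- do.call(rbind, out)
    attr(res, "unassigned") <- sum(!assigned)
    res
}
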