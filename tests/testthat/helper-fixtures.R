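suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
    library(Biostrings)
})

## Write a FASTQ file from parallel character vectors; returns the path.
writeFastqLines <- function(ids, seqs, quals, path = tempfile(fileext = ".fastq")) {
    stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
    writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
    path
}

## Phred integer vector -> Sanger quality string
q2str <- function(q) rawToChar(as.raw(q + 33L))

## Build a PoolCounts from a per-pool list of named allele count matrices.
## counts: list (one per pool) of sites x 4 matrices with columns A,C,G,T.
makeCounts <- function(chrom, pos, counts, roles,
                       ref = rep("A", length(pos))) {
    n <- length(pos)
    chrom <- rep_len(chrom, n)
    arr <- array(0L, c(n, length(counts), 6L))
    syncIdx <- c(A = 1L, T = 2L, C = 3L, G = 4L)
    for (p in seq_along(counts))
        for (b in c("A", "C", "G", "T"))
            arr[, p, syncIdx[[b]]] <- counts[[p]][, b]
    PoolCounts(chrom, pos, ref, arr, roles)
}

## One-pool-per-column shortcut: every pool shares the same allele pair.
## major/minor: sites x pools matrices of reads for the two alleles.
makeSnpCounts <- function(chrom, pos, major, minor, roles,
                          majorBase = "A", minorBase = "G") {
    nP <- length(roles)
    counts <- lapply(seq_len(nP), function(p) {
        m <- matrix(0L, length(pos), 4L,
                    dimnames = list(NULL, c("A", "C", "G", "T")))
        m[, majorBase] <- major[, p]
        m[, minorBase] <- minor[, p]
        m
    })
    makeCounts(chrom, pos, counts, roles)
}

## Independent two-tailed Fisher oracle: explicit enumeration of all
## tables with the observed margins, probabilities from lchoose().
fisherOracle <- function(a, b, c_, d) {
    r1 <- a + b; r2 <- c_ + d; k <- a + c_; N <- r1 + r2
    if (r1 == 0 || r2 == 0 || k == 0 || N - k == 0) return(1)
    xs <- max(0, k - r2):min(r1, k)
    logp <- lchoose(r1, xs) + lchoose(r2, k - xs) - lchoose(N, k)
    pr <- exp(logp)
    pobs <- pr[match(a, xs)]
    sum(pr[pr <= pobs * (1 + 1e-7)])
}

## Literal BH step-up oracle (independent of stats::p.adjust).
bhOracle <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
}

## Clamped running-sum trim oracle evaluated step by step.
mottOracle <- function(quals, A = 20, clamp = TRUE) {
    v <- 10^(-A / 10) - 10^(-quals / 10)
    s <- numeric(length(v))
    acc <- 0
    for (i in seq_along(v)) {
        acc <- acc + v[i]
        if (clamp && acc < 0) acc <- 0
        s[i] <- acc
    }
    if (!any(s > 0)) return(c(1L, 0L))
    first <- which(s > 0)[1L]
    c(first, max(which(s >= max(s) - 1e-12)))
}
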