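.defaultGenome <- function()
    stats::setNames(as.list(rep(2e6, 5)), paste0("chr", 1:5))

.defaultSweeps <- function() {
    ## three hard sweeps, aligned to 20-kb window boundaries
    GRanges(c("chr1", "chr3", "chr5"),
            IRanges(start = c(1000001L, 420001L, 1500001L),
                    end = c(1060000L, 480000L, 1540000L)))
}

#' Simulation configuration
#'
#' Describes the Pool-seq study design the generator emulates: four
#' domestic pools and one wild pool of ~30 diploid individuals each,
#' sequenced to ~30X per pool, with one polymorphic site per ~116 bp, a
#' neutral wild allele-frequency spectrum concentrated at low MAF, drifted
#' domestic frequencies, and planted hard-sweep regions in which the
#' domestic pools are fixed while the wild pool stays polymorphic.
#'
#' @slot genome named list of chromosome lengths (bp).
#' @slot nDomesticPools number of domestic pools (default 4; the wild pool
#'   is always single).
#' @slot poolSize diploid individuals per pool (default 30); sets the
#'   lowest representable allele frequency, 1/(2 * poolSize).
#' @slot coverage mean read depth per pool (default 30).
#' @slot errorRate per-base sequencing error probability (default 0.002),
#'   applied read-wise after allele sampling so the minor-allele-count
#'   filter has true errors to reject.
#' @slot snpDensity expected polymorphic sites per bp (default 1/116).
#' @slot backgroundDensity density of emitted monomorphic sites (default
#'   1/500) so error-driven false candidates exist at desk scale.
#' @slot driftC Balding--Nichols differentiation parameter for domestic
#'   pools (default 0.05); 0 means domestic frequencies equal wild.
#' @slot driftModel \code{"balding-nichols"} (Beta-distributed drift) or
#'   \code{"bottleneck"} (one binomial founder generation of
#'   \code{2 * poolSize} chromosomes per pool).
#' @slot sweeps GRanges of planted hard-sweep regions.
#' @slot seed integer random seed (mandatory).
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(genome = "list", nDomesticPools = "numeric",
                        poolSize = "numeric", coverage = "numeric",
                        errorRate = "numeric", snpDensity = "numeric",
                        backgroundDensity = "numeric", driftC = "numeric",
                        driftModel = "character", sweeps = "GRanges",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    g <- object@genome
    if (length(g) == 0L || is.null(names(g)) || any(!nzchar(names(g))))
        msg <- c(msg, "genome must be a named list of chromosome lengths")
    if (any(unlist(g) < 1)) msg <- c(msg, "chromosome lengths must be >= 1")
    for (s in c("nDomesticPools", "poolSize", "coverage"))
        if (slot(object, s) < 1) msg <- c(msg, paste(s, "must be >= 1"))
    if (object@errorRate < 0 || object@errorRate >= 1)
        msg <- c(msg, "errorRate must lie in [0, 1)")
    if (object@snpDensity <= 0 || object@snpDensity > 1)
        msg <- c(msg, "snpDensity must lie in (0, 1]")
    if (object@backgroundDensity < 0 || object@backgroundDensity > 1)
        msg <- c(msg, "backgroundDensity must lie in [0, 1]")
    if (object@driftC < 0 || object@driftC >= 1)
        msg <- c(msg, "driftC must lie in [0, 1)")
    if (!object@driftModel %in% c("balding-nichols", "bottleneck"))
        msg <- c(msg, "driftModel must be 'balding-nichols' or 'bottleneck'")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "a scalar integer seed is mandatory")
    sw <- object@sweeps
    if (length(sw)) {
        if (length(reduce(sw, ignore.strand = TRUE)) != length(sw))
            msg <- c(msg, "sweep regions must not overlap")
        bad <- !as.character(seqnames(sw)) %in% names(g)
        if (any(bad))
            msg <- c(msg, "sweep regions on chromosomes absent from genome")
        else {
            lens <- unlist(g)[as.character(seqnames(sw))]
            if (any(start(sw) < 1) || any(end(sw) > lens))
                msg <- c(msg, "sweep regions extend beyond the genome")
        }
    }
    if (length(msg)) msg else TRUE
})

#' @param genome,nDomesticPools,poolSize,coverage,errorRate,snpDensity,backgroundDensity,driftC,driftModel,seed
#'   see the slot descriptions.
#' @param sweeps planted sweep regions; when \code{NULL}, the default
#'   10-Mb genome gets three 40--60-kb regions and any custom genome gets
#'   none.
#' @return \code{simulationConfig} returns a
#'   \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(seed = 1)
#' cfg
#' @rdname SimulationConfig-class
#' @export
simulationConfig <- function(genome = .defaultGenome(),
                             nDomesticPools = 4, poolSize = 30,
                             coverage = 30, errorRate = 0.002,
                             snpDensity = 1 / 116,
                             backgroundDensity = 1 / 500,
                             driftC = 0.05,
                             driftModel = c("balding-nichols", "bottleneck"),
                             sweeps = NULL, seed) {
    if (missing(seed)) stop("a seed is mandatory for reproducibility")
    driftModel <- match.arg(driftModel)
    if (is.null(sweeps)) {
        sweeps <- if (identical(lapply(genome, as.numeric),
                                lapply(.defaultGenome(), as.numeric)))
            .defaultSweeps()
        else GRanges()
    }
    new("SimulationConfig", genome = as.list(genome),
        nDomesticPools = nDomesticPools, poolSize = poolSize,
        coverage = coverage, errorRate = errorRate,
        snpDensity = snpDensity, backgroundDensity = backgroundDensity,
        driftC = driftC, driftModel = driftModel, sweeps = sweeps,
        seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
    cat(sprintf(paste0(
        "SimulationConfig: %d chromosomes (%.1f Mb), %g domestic + 1 wild",
        " pools\n  pool size %g, coverage %gX, error %g, SNP density 1/%.0f,",
        " drift c=%g (%s)\n  %d planted sweep region(s), seed %d\n"),
        length(object@genome), sum(unlist(object@genome)) / 1e6,
        object@nDomesticPools, object@poolSize, object@coverage,
        object@errorRate, 1 / object@snpDensity, object@driftC,
        object@driftModel, length(object@sweeps), object@seed))
})

#' Ground truth underlying a simulated data set
#'
#' @slot sites GRanges of polymorphic sites with metadata columns
#'   \code{ref}, \code{alt}, \code{wildFreq} (alternate-allele frequency
#'   in the wild pool) and \code{inSweep}.
#' @slot domFreq sites x domestic-pools matrix of alternate-allele
#'   frequencies.
#' @slot sweepRegions the planted sweep intervals.
#' @slot strainSpecific integer site indices truly polymorphic in exactly
#'   one pool (list: one element per pool, domestic pools then wild).
#' @slot differentiated integer site indices where the pooled domestic
#'   frequency differs from the wild frequency by more than 0.2.
#' @exportClass GroundTruth
setClass("GroundTruth",
         representation(sites = "GRanges", domFreq = "matrix",
                        sweepRegions = "GRanges", strainSpecific = "list",
                        differentiated = "integer"))

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf(
        "GroundTruth: %d polymorphic sites, %d sweep region(s), %d differentiated site(s)\n",
        length(object@sites), length(object@sweepRegions),
        length(object@differentiated)))
})

## Memoryless site placement: geometric gaps at the given density.
.placeSites <- function(len, density) {
    if (density <= 0) return(integer())
    expected <- len * density
    n <- ceiling(expected + 4 * sqrt(expected) + 10)
    pos <- cumsum(stats::rgeom(n, density) + 1L)
    while (length(pos) && pos[length(pos)] <= len) {
        extra <- cumsum(stats::rgeom(n, density) + 1L) + pos[length(pos)]
        pos <- c(pos, extra)
    }
    pos[pos <= len]
}

## Neutral-like minor allele frequency spectrum: density proportional to
## 1/f on [1/(2*poolSize), 0.5]; closed-form inverse CDF for sampling and
## for distributional tests.
.sampleWildMaf <- function(n, poolSize) {
    f0 <- 1 / (2 * poolSize)
    f0 * (0.5 / f0)^stats::runif(n)
}

#' Simulate true per-pool allele frequencies
#'
#' Places polymorphic sites by a memoryless spacing process at the
#' configured SNP density; draws the wild minor allele frequency from a
#' neutral-like spectrum with density proportional to \eqn{1/f} on
#' \eqn{[1/(2 N), 0.5]} (concentrated at low MAF) and orients the
#' alternate allele at random; draws each domestic pool's frequency from
#' a Balding--Nichols Beta distribution around the wild frequency with
#' differentiation \code{driftC} (or one binomial founder generation in
#' the bottleneck model). Inside planted sweep regions every domestic
#' pool is fixed (frequency exactly 0 or 1, the same allele across
#' pools — the wild major allele) while the wild pool stays polymorphic.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @return a \linkS4class{GroundTruth}.
#' @examples
#' truth <- simulateFrequencies(simulationConfig(seed = 1))
#' truth
#' @export
simulateFrequencies <- function(cfg) {
    set.seed(cfg@seed)
    chroms <- names(cfg@genome)
    posList <- lapply(chroms, function(ch)
        .placeSites(cfg@genome[[ch]], cfg@snpDensity))
    n <- sum(lengths(posList))
    sites <- GRanges(rep(chroms, lengths(posList)),
                     IRanges(unlist(posList), width = 1L))
    refIdx <- sample.int(4L, n, replace = TRUE)
    altIdx <- (refIdx - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L
    f <- .sampleWildMaf(n, cfg@poolSize)
    wildFreq <- ifelse(stats::runif(n) < 0.5, f, 1 - f)
    nD <- cfg@nDomesticPools
    domFreq <- matrix(0, n, nD)
    if (cfg@driftC == 0) {
        domFreq[] <- wildFreq
    } else if (cfg@driftModel == "balding-nichols") {
        c_ <- cfg@driftC
        a <- wildFreq * (1 - c_) / c_
        b <- (1 - wildFreq) * (1 - c_) / c_
        for (j in seq_len(nD)) domFreq[, j] <- stats::rbeta(n, a, b)
    } else {
        chromN <- 2L * cfg@poolSize
        for (j in seq_len(nD))
            domFreq[, j] <- stats::rbinom(n, chromN, wildFreq) / chromN
    }
    inSweep <- countOverlaps(sites, cfg@sweeps, ignore.strand = TRUE) > 0L
    if (any(inSweep))        # fix the wild major allele across all pools
        domFreq[inSweep, ] <- as.numeric(wildFreq[inSweep] >= 0.5)
    mcols(sites) <- DataFrame(ref = .ACGT[refIdx], alt = .ACGT[altIdx],
                              wildFreq = wildFreq, inSweep = inSweep)
    allFreq <- cbind(domFreq, wildFreq)
    poly <- allFreq > 0 & allFreq < 1
    onePoly <- rowSums(poly) == 1L
    strainSpecific <- lapply(seq_len(nD + 1L), function(j)
        which(onePoly & poly[, j]))
    pooledDom <- rowMeans(domFreq)
    differentiated <- which(abs(pooledDom - wildFreq) > 0.2)
    new("GroundTruth", sites = sites, domFreq = domFreq,
        sweepRegions = cfg@sweeps, strainSpecific = strainSpecific,
        differentiated = as.integer(differentiated))
}

## Split `flips` errors uniformly over three target bases via a chain of
## binomials (vectorised; avoids per-site rmultinom calls).
.splitThree <- function(flips) {
    x1 <- stats::rbinom(length(flips), flips, 1 / 3)
    x2 <- stats::rbinom(length(flips), flips - x1, 1 / 2)
    cbind(x1, x2, flips - x1 - x2)
}

#' Simulate per-pool read counts from ground-truth frequencies
#'
#' Per pool and site, read depth is Poisson(\code{coverage}) and
#' alternate-allele reads are Binomial(depth, pool frequency). Each read
#' is then flipped to a uniformly chosen other base with probability
#' \code{errorRate}, so monomorphic and fixed sites still show spurious
#' minor counts for the filters to reject. Monomorphic background sites
#' (reference-fixed in every pool) are interleaved at
#' \code{backgroundDensity}. Output is byte-identical for identical
#' configurations (same seed).
#'
#' @param truth a \linkS4class{GroundTruth} from
#'   \code{\link{simulateFrequencies}}.
#' @param cfg the same \linkS4class{SimulationConfig}.
#' @return a \linkS4class{PoolCounts} with the domestic pools first and
#'   the wild pool last.
#' @examples
#' cfg <- simulationConfig(genome = list(chr1 = 5e4), seed = 2)
#' simulateCounts(simulateFrequencies(cfg), cfg)
#' @export
simulateCounts <- function(truth, cfg) {
    set.seed(cfg@seed + 1L)
    nD <- cfg@nDomesticPools
    ## interleave monomorphic background sites
    chroms <- names(cfg@genome)
    bgList <- lapply(chroms, function(ch)
        .placeSites(cfg@genome[[ch]], cfg@backgroundDensity))
    bg <- GRanges(rep(chroms, lengths(bgList)),
                  IRanges(unlist(bgList), width = 1L))
    if (length(bg)) {
        snpPos <- paste0(as.character(seqnames(truth@sites)), ":",
                         start(truth@sites))
        bgPos <- paste0(as.character(seqnames(bg)), ":", start(bg))
        bg <- bg[!bgPos %in% snpPos]
    }
    nS <- length(truth@sites)
    nB <- length(bg)
    chrom <- c(as.character(seqnames(truth@sites)), as.character(seqnames(bg)))
    pos <- c(start(truth@sites), start(bg))
    refIdx <- c(match(mcols(truth@sites)$ref, .ACGT),
                sample.int(4L, nB, replace = TRUE))
    altIdx <- c(match(mcols(truth@sites)$alt, .ACGT),
                rep(1L, nB))                      # unused: freq 0
    freq <- cbind(truth@domFreq, mcols(truth@sites)$wildFreq)
    freq <- rbind(freq, matrix(0, nB, nD + 1L))
    n <- nS + nB
    counts <- array(0L, c(n, nD + 1L, 6L))
    for (p in seq_len(nD + 1L)) {
        depth <- stats::rpois(n, cfg@coverage)
        alt <- stats::rbinom(n, depth, freq[, p])
        ref <- depth - alt
        base <- matrix(0L, n, 4L)
        base[cbind(seq_len(n), refIdx)] <- ref
        base[cbind(seq_len(n), altIdx)] <- base[cbind(seq_len(n), altIdx)] + alt
        if (cfg@errorRate > 0) {
            for (k in seq_len(4L)) {
                src <- base[, k]
                flips <- stats::rbinom(n, src, cfg@errorRate)
                spread <- .splitThree(flips)
                base[, k] <- base[, k] - flips
                others <- setdiff(seq_len(4L), k)
                for (m in seq_len(3L))
                    base[, others[m]] <- base[, others[m]] + spread[, m]
            }
        }
        ## sync order A, T, C, G (N and deletions never simulated)
        counts[, p, 1L] <- base[, 1L]   # A
        counts[, p, 2L] <- base[, 4L]   # T
        counts[, p, 3L] <- base[, 2L]   # C
        counts[, p, 4L] <- base[, 3L]   # G
    }
    ord <- order(match(chrom, chroms), pos)
    PoolCounts(chrom[ord], pos[ord], .ACGT[refIdx][ord],
               counts[ord, , , drop = FALSE],
               roles = c(rep("domestic", nD), "wild"),
               poolNames = c(paste0("domestic", seq_len(nD)), "wild"))
}

#' Simulate FASTQ reads with a planted quality profile
#'
#' Good reads carry a high-quality core (Phred 34--40) with a short
#' low-quality 3' tail that the trimmer removes; a configurable fraction
#' of bad reads are low quality throughout (Phred 2--8, with occasional
#' Ns) and are expected to be discarded entirely.
#'
#' @param cfg a \linkS4class{SimulationConfig} (supplies the seed).
#' @param nReads number of reads (default 500).
#' @param readLength read length in bp (default 100).
#' @param badFraction fraction of planted bad reads (default 0.04).
#' @param tailLength low-quality 3' tail length on good reads (default 4).
#' @param path optional FASTQ output path.
#' @return list with \code{reads} (a
#'   \link[Biostrings]{QualityScaledDNAStringSet}), \code{truthKeep}
#'   (logical: read planted as good) and \code{path} (or \code{NA}).
#' @export
simulateFastq <- function(cfg, nReads = 500, readLength = 100,
                          badFraction = 0.04, tailLength = 4, path = NULL) {
    set.seed(cfg@seed + 2L)
    bad <- stats::runif(nReads) < badFraction
    seqs <- vapply(seq_len(nReads), function(i) {
        b <- sample(.ACGT, readLength, replace = TRUE)
        if (bad[i]) {
            nPos <- stats::runif(readLength) < 0.05
            b[nPos] <- "N"
        }
        paste(b, collapse = "")
    }, character(1))
    quals <- vapply(seq_len(nReads), function(i) {
        q <- if (bad[i]) sample(2:8, readLength, replace = TRUE)
        else {
            core <- sample(34:40, readLength, replace = TRUE)
            if (tailLength > 0)
                core[(readLength - tailLength + 1L):readLength] <-
                    sample(2:10, tailLength, replace = TRUE)
            core
        }
        rawToChar(as.raw(q + 33L))
    }, character(1))
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- sprintf("read%05d", seq_len(nReads))
    reads <- Biostrings::QualityScaledDNAStringSet(
        dna, Biostrings::PhredQuality(quals))
    if (!is.null(path)) writeFastq(reads, path)
    list(reads = reads, truthKeep = !bad,
         path = if (is.null(path)) NA_character_ else path)
}

#' Generate a synthetic gene annotation
#'
#' Places non-overlapping genes (each with a central CDS) uniformly along
#' the genome, then arranges planted sweep regions so that all but every
#' third one contain a gene (background genes overlapping a sweep are
#' removed first), giving both gene-bearing and gene-desert sweeps.
#'
#' @param cfg a \linkS4class{SimulationConfig}.
#' @param geneDensity expected genes per bp outside sweeps (default
#'   1/50000).
#' @param geneLength gene length in bp (default 2000).
#' @param path optional GFF3 output path (written via rtracklayer).
#' @return a \link[GenomicRanges]{GRanges} with \code{type} (gene/CDS),
#'   \code{ID} and \code{Name} columns; gene and CDS rows of one gene
#'   share a \code{Name}.
#' @export
makeAnnotation <- function(cfg, geneDensity = 1 / 50000, geneLength = 2000,
                           path = NULL) {
    set.seed(cfg@seed + 3L)
    chroms <- names(cfg@genome)
    mkGR <- function(ch, ranges)
        GRanges(factor(ch, levels = chroms), ranges)
    genes <- mkGR(character(), IRanges())
    if (geneDensity > 0) {
        for (ch in chroms) {
            len <- cfg@genome[[ch]]
            nGene <- stats::rpois(1L, len * geneDensity)
            if (nGene == 0L) next
            ## grid placement guarantees non-overlap
            slots <- seq(1L, max(1L, len - geneLength), by = 2L * geneLength)
            nGene <- min(nGene, length(slots))
            starts <- sort(sample(slots, nGene))
            genes <- c(genes, mkGR(ch, IRanges(starts, width = geneLength)))
        }
    }
    if (length(cfg@sweeps)) {
        genes <- genes[countOverlaps(genes, cfg@sweeps,
                                     ignore.strand = TRUE) == 0L]
        withGene <- which(seq_along(cfg@sweeps) %% 3L != 0L)
        for (i in withGene) {
            sw <- cfg@sweeps[i]
            mid <- start(sw) + (width(sw) - geneLength) %/% 2L
            genes <- c(genes, mkGR(as.character(seqnames(sw)),
                                   IRanges(mid, width = geneLength)))
        }
    }
    genes <- sort(genes, ignore.strand = TRUE)
    if (length(genes) == 0L) {
        out <- GRanges()
        mcols(out) <- DataFrame(type = character(), ID = character(),
                                Name = character())
        if (!is.null(path)) rtracklayer::export(out, path, format = "gff3")
        return(out)
    }
    gid <- sprintf("gene%04d", seq_along(genes))
    cds <- IRanges::narrow(genes,
                           start = 1L + geneLength %/% 4L,
                           end = geneLength - geneLength %/% 4L)
    geneRows <- genes
    mcols(geneRows) <- DataFrame(type = "gene", ID = gid, Name = gid)
    cdsRows <- cds
    mcols(cdsRows) <- DataFrame(type = "CDS", ID = gid, Name = gid)
    mcols(geneRows)$phase <- NA_integer_
    mcols(cdsRows)$phase <- 0L
    out <- sort(c(geneRows, cdsRows), ignore.strand = TRUE)
    mcols(out)$type <- factor(mcols(out)$type, levels = c("gene", "CDS"))
    if (!is.null(path)) rtracklayer::export(out, path, format = "gff3")
    out
}

#' Run the full scan on synthetic or real pooled counts
#'
#' Convenience wrapper chaining candidate calling, the three-factor
#' filter, domestic-vs-wild differentiation testing and the windowed Hp
#' sweep scan (with optional gene annotation of called regions).
#'
#' @param counts a \linkS4class{PoolCounts}.
#' @param criteria a \linkS4class{FilterCriteria} (default 30/300/5).
#' @param alpha FDR level for significant SNPs (default 0.01).
#' @param windowSize,step,minSnps,threshold,cap see \code{\link{windowHp}}
#'   and \code{\link{callSweeps}}.
#' @param features optional annotation GRanges for
#'   \code{\link{categorizeLocation}} and \code{\link{annotateSweeps}}.
#' @return list with elements \code{candidates}, \code{snps} (filtered),
#'   \code{filterStats}, \code{significant}, \code{windows} and
#'   \code{sweeps}.
#' @export
runSweepPipeline <- function(counts, criteria = filterCriteria(30, 300, 5),
                             alpha = 0.01, windowSize = 20000,
                             step = windowSize, minSnps = 5, threshold = 4,
                             cap = 7, features = NULL) {
    cand <- callCandidates(counts)
    flt <- applyFilter(cand, criteria,
                       depthDistribution = siteDepth(counts))
    sig <- findSignificant(flt$snps, alpha = alpha)$significant
    if (!is.null(features))
        sig <- categorizeLocation(sig, features)
    win <- windowHp(sig, windowSize = windowSize, step = step,
                    minSnps = minSnps, cap = cap)
    sw <- callSweeps(win, threshold = threshold)
    if (!is.null(features))
        sw <- annotateSweeps(sw, features)
    list(candidates = cand, snps = flt$snps, filterStats = flt$stats,
         significant = sig, windows = win, sweeps = sw)
}
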