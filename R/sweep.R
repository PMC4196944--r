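#' Transform pooled heterozygosity to a sweep score
#'
#' Returns \eqn{-\log_2(H_p)}; a window with \eqn{H_p = 0} (complete
#' fixation, where the logarithm diverges) is assigned the cap value
#' (default 7), the maximum score.
#'
#' @param hp numeric pooled heterozygosity values in \eqn{[0, 0.5]}.
#' @param cap score assigned when \code{hp} is exactly 0.
#' @return numeric transformed scores.
#' @examples
#' transformHp(c(0.5, 0.012, 0))  # 1, 6.38, 7
#' @export
transformHp <- function(hp, cap = 7) {
    if (any(hp < 0) || any(hp > 0.5 + 1e-12))
        stop("Hp must lie in [0, 0.5]")
    out <- ifelse(hp > 0, -log2(hp), cap)
    out
}

#' Windowed pooled heterozygosity over significant SNPs
#'
#' Tiles each chromosome with windows of \code{windowSize} bp starting at
#' its first base (advancing by \code{step}; the default non-overlapping
#' tiling gives each SNP to exactly one window) and computes, per window,
#' \deqn{H_p = 2 \Sigma n_{MAJ} \Sigma n_{MIN} / (\Sigma n_{MAJ} +
#'   \Sigma n_{MIN})^2}
#' where the sums run over the in-scope pools' major and minor allele
#' reads of all contained SNPs. Major/minor orientation is recomputed per
#' SNP within the in-scope counts (by default the domestic pools, whose
#' allele balance the scan interrogates; the wild pool never contributes),
#' not inherited from the catalogue-wide orientation. Windows containing
#' fewer than \code{minSnps} SNPs are omitted.
#'
#' @param snps a \linkS4class{SnpCatalog}, typically the significant subset
#'   from \code{\link{findSignificant}}.
#' @param pools pool indices in scope; default the domestic pools.
#' @param windowSize,step window width and advance in bp (defaults 20 kb,
#'   non-overlapping).
#' @param minSnps minimum SNPs per emitted window (default 5).
#' @param cap transformed score assigned to zero-heterozygosity windows.
#' @return a \link[GenomicRanges]{GRanges} of emitted windows with
#'   metadata columns \code{nSnps}, \code{sumMaj}, \code{sumMin},
#'   \code{hp}, \code{hpTransformed}.
#' @export
windowHp <- function(snps, pools = domesticPools(snps),
                     windowSize = 20000, step = windowSize,
                     minSnps = 5, cap = 7) {
    if (windowSize <= 0 || step <= 0)
        stop("windowSize and step must be positive")
    sMaj <- rowSums(majorCounts(snps)[, pools, drop = FALSE])
    sMin <- rowSums(minorCounts(snps)[, pools, drop = FALSE])
    hi <- pmax(sMaj, sMin)    # in-scope reorientation
    lo <- pmin(sMaj, sMin)
    chrom <- as.character(seqnames(rowRanges(snps)))
    pos <- start(rowRanges(snps))
    res <- lapply(unique(chrom), function(ch) {
        sel <- chrom == ch
        p <- pos[sel]
        if (step == windowSize) {
            idx <- (p - 1L) %/% windowSize        # one window per SNP
            key <- factor(idx)
            starts <- as.integer(levels(key)) * windowSize + 1L
            n <- as.integer(table(key))
            SM <- unname(rowsum(hi[sel], key)[, 1L])
            Sm <- unname(rowsum(lo[sel], key)[, 1L])
        } else {
            starts0 <- seq(1L, max(p), by = step)
            w <- GRanges(ch, IRanges(starts0, width = windowSize))
            ov <- findOverlaps(GRanges(ch, IRanges(p, width = 1L)), w)
            key <- factor(S4Vectors::subjectHits(ov),
                          levels = seq_along(starts0))
            n <- as.integer(table(key))
            keep0 <- n > 0L
            SM <- Sm <- numeric(length(starts0))
            agg <- rowsum(hi[sel][S4Vectors::queryHits(ov)],
                          S4Vectors::subjectHits(ov))
            SM[as.integer(rownames(agg))] <- agg[, 1L]
            agg <- rowsum(lo[sel][S4Vectors::queryHits(ov)],
                          S4Vectors::subjectHits(ov))
            Sm[as.integer(rownames(agg))] <- agg[, 1L]
            starts <- starts0[keep0]; n <- n[keep0]
            SM <- SM[keep0]; Sm <- Sm[keep0]
        }
        keep <- n >= minSnps
        if (!any(keep)) return(NULL)
        tot <- SM[keep] + Sm[keep]
        hp <- ifelse(tot > 0, 2 * SM[keep] * Sm[keep] / tot^2, 0)
        gr <- GRanges(factor(ch, levels = unique(chrom)),
                      IRanges(starts[keep], width = windowSize))
        mcols(gr) <- DataFrame(nSnps = n[keep],
                               sumMaj = as.integer(SM[keep]),
                               sumMin = as.integer(Sm[keep]),
                               hp = hp,
                               hpTransformed = transformHp(hp, cap))
        gr
    })
    res <- res[!vapply(res, is.null, logical(1))]
    if (!length(res)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(nSnps = integer(), sumMaj = integer(),
                               sumMin = integer(), hp = numeric(),
                               hpTransformed = numeric())
        return(gr)
    }
    sort(do.call(c, res), ignore.strand = TRUE)
}

#' Call putative selective sweep regions
#'
#' Selects windows whose transformed score reaches \code{threshold}
#' (inclusive) and merges adjacent or overlapping selected windows on the
#' same chromosome into regions. Regions are ranked by their minimum
#' window Hp ascending — equivalently by peak transformed score
#' descending, with zero-heterozygosity (capped) windows ranking first
#' regardless of the cap value chosen.
#'
#' @param windows the GRanges from \code{\link{windowHp}}.
#' @param threshold minimum transformed Hp score (default 4).
#' @return a \link[GenomicRanges]{GRanges} of sweep regions with metadata
#'   columns \code{minHp}, \code{maxTransformed} and \code{windowIds}
#'   (indices into \code{windows}).
#' @export
callSweeps <- function(windows, threshold = 4) {
    selIdx <- which(mcols(windows)$hpTransformed >= threshold)
    sel <- windows[selIdx]
    if (length(sel) == 0L) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(minHp = numeric(), maxTransformed = numeric(),
                               windowIds = IRanges::IntegerList())
        return(gr)
    }
    reg <- reduce(sel, min.gapwidth = 1L, ignore.strand = TRUE)
    ov <- findOverlaps(sel, reg, ignore.strand = TRUE)
    byReg <- split(S4Vectors::queryHits(ov), S4Vectors::subjectHits(ov))
    minHp <- vapply(byReg, function(i) min(mcols(sel)$hp[i]), numeric(1))
    maxT <- vapply(byReg, function(i)
        max(mcols(sel)$hpTransformed[i]), numeric(1))
    ids <- IRanges::IntegerList(lapply(byReg, function(i) selIdx[i]))
    mcols(reg) <- DataFrame(minHp = minHp, maxTransformed = maxT,
                            windowIds = ids)
    reg[order(minHp)]
}

#' Attach overlapping genes to sweep regions
#'
#' Any overlap (down to a single bp) attaches a feature; regions in gene
#' deserts keep empty gene lists. Pass gene-level features (duplicate
#' feature ids, e.g. a gene and its CDS rows sharing an id, are collapsed).
#'
#' @param regions the GRanges from \code{\link{callSweeps}}.
#' @param features a \link[GenomicRanges]{GRanges} from
#'   \code{\link{readAnnotation}}.
#' @return \code{regions} with a \code{genes} CharacterList column.
#' @export
annotateSweeps <- function(regions, features) {
    features <- .asFeatures(features)
    ov <- findOverlaps(regions, features, ignore.strand = TRUE)
    ids <- as.character(mcols(features)$feature_id)
    genes <- rep(list(character()), length(regions))
    if (length(ov)) {
        byReg <- split(ids[S4Vectors::subjectHits(ov)],
                       S4Vectors::queryHits(ov))
        genes[as.integer(names(byReg))] <-
            lapply(byReg, function(g) sort(unique(g)))
    }
    mcols(regions)$genes <- IRanges::CharacterList(genes)
    regions
}
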