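## Stack the four nucleotide assays into a sites x pools x 4 array
## (columns ordered A, C, G, T so ties break alphabetically).
.acgtArray <- function(x, pools) {
    n <- nrow(x)
    arr <- array(0L, c(n, length(pools), 4L))
    for (k in seq_along(.ACGT))
        arr[, , k] <- assay(x, .ACGT[k])[, pools, drop = FALSE]
    arr
}

#' Identify candidate SNPs from pooled counts
#'
#' For every site, A/C/G/T read counts are summed over the in-scope pools;
#' the highest-count allele is the major allele and the second the minor
#' (ties broken alphabetically). A site becomes a candidate when the summed
#' minor allele count reaches \code{minMinor} (default 2, the relaxed floor
#' of the filter-optimization grid). Sites where a third allele reaches the
#' same floor are dropped: the catalogue is strictly biallelic, and a third
#' allele carrying that much read support is no longer credible as
#' sequencing noise. N and deletion counts never form alleles.
#'
#' @param x a \linkS4class{PoolCounts} object.
#' @param scope \code{"combined"} (one catalogue, alleles oriented on the
#'   summed counts — the default) or \code{"per_pool"} (one catalogue per
#'   pool, oriented and thresholded within that pool alone).
#' @param pools pool indices summed in combined scope; default all pools.
#' @param minMinor candidate floor for the summed minor allele count.
#' @return a \linkS4class{SnpCatalog} (combined scope) or a named list of
#'   per-pool \linkS4class{SnpCatalog}s. RowData carries \code{majorReads} and
#'   \code{minorReads}, the in-scope summed allele reads the downstream
#'   filter thresholds.
#' @examples
#' cfg <- simulationConfig(genome = list(chr1 = 2e4), seed = 7)
#' pc <- simulateCounts(simulateFrequencies(cfg), cfg)
#' callCandidates(pc)
#' @export
callCandidates <- function(x, scope = c("combined", "per_pool"),
                           pools = seq_len(ncol(x)), minMinor = 2) {
    scope <- match.arg(scope)
    if (scope == "per_pool") {
        out <- lapply(seq_len(ncol(x)), function(p)
            callCandidates(x, scope = "combined", pools = p,
                           minMinor = minMinor))
        names(out) <- colnames(x)
        return(out)
    }
    n <- nrow(x)
    arr <- .acgtArray(x, seq_len(ncol(x)))
    M <- vapply(seq_len(4L), function(k)
        rowSums(arr[, pools, k, drop = FALSE]), numeric(n))
    if (n == 0L) M <- matrix(0L, 0L, 4L)
    if (n == 1L) M <- matrix(M, 1L, 4L)
    majIdx <- max.col(M, ties.method = "first")
    tmp <- M
    tmp[cbind(seq_len(n), majIdx)] <- -1L
    minIdx <- max.col(tmp, ties.method = "first")
    tmp[cbind(seq_len(n), minIdx)] <- -1L
    thirdCount <- tmp[cbind(seq_len(n), max.col(tmp, ties.method = "first"))]
    majorReads <- M[cbind(seq_len(n), majIdx)]
    minorReads <- M[cbind(seq_len(n), minIdx)]
    keep <- which(minorReads >= minMinor & thirdCount < minMinor)
    majMat <- minMat <- matrix(0L, length(keep), ncol(x),
                               dimnames = list(NULL, colnames(x)))
    for (p in seq_len(ncol(x))) {
        majMat[, p] <- arr[cbind(keep, p, majIdx[keep])]
        minMat[, p] <- arr[cbind(keep, p, minIdx[keep])]
    }
    rr <- rowRanges(x)[keep]
    rd <- DataFrame(
        ref = rowData(x)$ref[keep],
        majorAllele = .ACGT[majIdx[keep]],
        minorAllele = .ACGT[minIdx[keep]],
        majorReads = as.integer(majorReads[keep]),
        minorReads = as.integer(minorReads[keep]),
        thirdCount = as.integer(pmax(thirdCount[keep], 0L)),
        totalDepth = as.integer(rowSums(M)[keep]),
        maf = minorReads[keep] / (majorReads[keep] + minorReads[keep]))
    mcols(rr) <- rd
    se <- SummarizedExperiment(
        assays = list(majorCount = majMat, minorCount = minMat),
        rowRanges = rr, colData = colData(x))
    new("SnpCatalog", se)
}

.resolveMaxDepth <- function(criteria, depthDistribution) {
    if (!is.na(criteria@maxDepth)) return(criteria@maxDepth)
    if (is.null(depthDistribution))
        stop("a quantile max-depth spec needs a site depth distribution")
    unname(stats::quantile(depthDistribution,
                           1 - criteria@maxDepthQuantile))
}

#' Apply the three-factor SNP quality filter
#'
#' Keeps candidates whose total in-scope depth lies within
#' \code{[minDepth, maxDepth]} and whose summed minor allele read count
#' reaches \code{minMinor}; sites whose third-allele support reaches
#' \code{minMinor} are dropped (biallelic enforcement). A quantile
#' max-depth spec (\code{"top2\%"}) is resolved to the corresponding upper
#' percentile of \code{depthDistribution}.
#'
#' The reported \code{pctReadsIncluded} is depth-weighted site coverage
#' retained: the summed depth of sites passing the two depth bounds over
#' the summed depth of all sites in \code{depthDistribution}, times 100.
#'
#' @param snps a candidate \linkS4class{SnpCatalog} from
#'   \code{\link{callCandidates}}.
#' @param criteria a \linkS4class{FilterCriteria}.
#' @param depthDistribution site depths used both to resolve quantile
#'   max-depth specs and as the denominator of \code{pctReadsIncluded};
#'   defaults to the candidates' own depths, but passing the depths of all
#'   sync sites (including non-candidates) reproduces whole-dataset
#'   coverage accounting.
#' @return list with \code{snps} (the filtered \linkS4class{SnpCatalog}) and
#'   \code{stats} (data.frame: nSnps, pctReadsIncluded, resolvedMaxDepth).
#' @examples
#' cfg <- simulationConfig(genome = list(chr1 = 2e4), seed = 7)
#' pc <- simulateCounts(simulateFrequencies(cfg), cfg)
#' cand <- callCandidates(pc)
#' applyFilter(cand, filterCriteria(30, 300, 5))$stats
#' @export
applyFilter <- function(snps, criteria, depthDistribution = NULL) {
    if (is.null(depthDistribution)) depthDistribution <- totalDepth(snps)
    maxD <- .resolveMaxDepth(criteria, depthDistribution)
    if (maxD <= criteria@minDepth)
        stop("resolved max depth (", maxD, ") does not exceed min depth")
    d <- totalDepth(snps)
    inDepth <- d >= criteria@minDepth & d <= maxD
    keep <- inDepth &
        rowData(snps)$minorReads >= criteria@minMinor &
        rowData(snps)$thirdCount < criteria@minMinor
    pct <- 100 * sum(depthDistribution[depthDistribution >= criteria@minDepth &
                                       depthDistribution <= maxD]) /
        sum(depthDistribution)
    list(snps = snps[keep, ],
         stats = data.frame(nSnps = sum(keep),
                            pctReadsIncluded = pct,
                            resolvedMaxDepth = maxD))
}

#' Evaluate a grid of filter criteria
#'
#' Applies each criteria set to the same candidate catalogue and tabulates
#' SNP counts and the percentage of reads included, reproducing
#' \code{\link{applyFilter}} exactly row by row.
#'
#' @inheritParams applyFilter
#' @param criteriaList list of \linkS4class{FilterCriteria}.
#' @return data.frame, one row per criteria set: minDepth, maxDepth
#'   (display form), minMinor, resolvedMaxDepth, pctReadsIncluded, nSnps.
#' @export
criteriaGrid <- function(snps, criteriaList, depthDistribution = NULL) {
    stopifnot(length(criteriaList) >= 1L)
    rows <- lapply(criteriaList, function(cr) {
        st <- applyFilter(snps, cr, depthDistribution)$stats
        data.frame(
            minDepth = cr@minDepth,
            maxDepth = if (is.na(cr@maxDepth))
                sprintf("top%g%%", 100 * cr@maxDepthQuantile)
            else format(cr@maxDepth),
            minMinor = cr@minMinor,
            resolvedMaxDepth = st$resolvedMaxDepth,
            pctReadsIncluded = st$pctReadsIncluded,
            nSnps = st$nSnps)
    })
    do.call(rbind, rows)
}

#' Minor allele frequency spectrum
#'
#' Bins SNP minor allele frequencies into left-open, right-closed intervals
#' (the first bin additionally includes an exact 0), and reports the count
#' of SNPs with MAF exactly 0.5 separately; that count is also inside the
#' last bin, so bin counts always sum to the SNP total.
#'
#' @param snps a \linkS4class{SnpCatalog}.
#' @param binEdges increasing numeric bin edges in \eqn{[0, 0.5]}.
#' @return data.frame with \code{lower}, \code{upper}, \code{count}; the
#'   exact-0.5 count is attached as attribute \code{"exactHalf"}.
#' @examples
#' cfg <- simulationConfig(genome = list(chr1 = 2e4), seed = 7)
#' snps <- callCandidates(simulateCounts(simulateFrequencies(cfg), cfg))
#' mafSpectrum(snps)
#' @export
mafSpectrum <- function(snps, binEdges = c(0, .05, .10, .20, .30, .40, .50)) {
    stopifnot(is.numeric(binEdges), !is.unsorted(binEdges, strictly = TRUE))
    m <- maf(snps)
    bins <- cut(m, binEdges, right = TRUE, include.lowest = TRUE)
    out <- data.frame(lower = binEdges[-length(binEdges)],
                      upper = binEdges[-1L],
                      count = as.integer(table(bins)))
    attr(out, "exactHalf") <- sum(m == 0.5)
    out
}

#' Classify SNPs as common, strain-specific or unclassifiable
#'
#' Per-pool calling with per-pool depth criteria. A site is polymorphic in
#' a pool when its per-pool depth lies within the criteria bounds and the
#' pool's minor allele count reaches \code{minMinor}; it has qualifying
#' depth when the depth bounds alone are met. Common SNPs are polymorphic
#' in every pool. Strain-specific SNPs are polymorphic in exactly one pool
#' while every other pool has qualifying depth and stays below the minor
#' count floor (monomorphic with adequate evidence). Sites failing depth in
#' any other pool cannot be certified monomorphic there and fall into
#' \code{other}.
#'
#' @param x a \linkS4class{PoolCounts} object.
#' @param criteria a \linkS4class{FilterCriteria} applied per pool;
#'   quantile max-depth specs are resolved against each pool's own depth
#'   distribution.
#' @return list with GRanges elements: \code{common},
#'   \code{strainSpecific} (a named list, one per pool) and \code{other};
#'   the universe is all sites polymorphic in at least one pool.
#' @export
classifyStrainSnps <- function(x, criteria) {
    nP <- ncol(x)
    n <- nrow(x)
    arr <- .acgtArray(x, seq_len(nP))
    poly <- qual <- matrix(FALSE, n, nP)
    for (p in seq_len(nP)) {
        M <- arr[, p, , drop = TRUE]
        if (n == 1L) M <- matrix(M, 1L)
        d <- rowSums(M)
        maxD <- .resolveMaxDepth(criteria, d)
        qual[, p] <- d >= criteria@minDepth & d <= maxD
        tmp <- M
        tmp[cbind(seq_len(n), max.col(tmp, ties.method = "first"))] <- -1L
        second <- tmp[cbind(seq_len(n), max.col(tmp, ties.method = "first"))]
        tmp[cbind(seq_len(n), max.col(tmp, ties.method = "first"))] <- -1L
        third <- tmp[cbind(seq_len(n), max.col(tmp, ties.method = "first"))]
        poly[, p] <- qual[, p] & second >= criteria@minMinor &
            third < criteria@minMinor
    }
    nPoly <- rowSums(poly)
    anyPoly <- nPoly > 0L
    common <- nPoly == nP
    specificPool <- rep(NA_integer_, n)
    one <- which(nPoly == 1L)
    if (length(one)) {
        pool <- max.col(poly[one, , drop = FALSE], ties.method = "first")
        othersQual <- vapply(seq_along(one), function(k)
            all(qual[one[k], -pool[k]]), logical(1))
        specificPool[one[othersQual]] <- pool[othersQual]
    }
    rr <- rowRanges(x)
    spec <- lapply(seq_len(nP), function(p)
        rr[which(!is.na(specificPool) & specificPool == p)])
    names(spec) <- colnames(x)
    other <- anyPoly & !common & is.na(specificPool)
    list(common = rr[common], strainSpecific = spec, other = rr[other])
}

#' Summarise per-strain SNP totals
#'
#' Reporting-layer arithmetic for per-strain catalogues: the percentage of
#' each strain's quality SNPs that are specific to it, rounded to one
#' decimal.
#'
#' @param qualitySnps integer vector of per-strain quality SNP counts.
#' @param strainSpecific integer vector of per-strain specific SNP counts.
#' @param strains strain names; defaults to names of \code{qualitySnps}.
#' @return data.frame: strain, qualitySnps, strainSpecific, percentage
#'   (1 decimal).
#' @examples
#' strainSnpSummary(c(Hatchery = 7100489, USDA103 = 4898477),
#'                  c(66487, 143126))
#' @export
strainSnpSummary <- function(qualitySnps, strainSpecific,
                             strains = names(qualitySnps)) {
    stopifnot(length(qualitySnps) == length(strainSpecific))
    if (is.null(strains)) strains <- paste0("strain", seq_along(qualitySnps))
    data.frame(strain = strains,
               qualitySnps = qualitySnps,
               strainSpecific = strainSpecific,
               percentage = round(100 * strainSpecific / qualitySnps, 1),
               row.names = NULL)
}
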