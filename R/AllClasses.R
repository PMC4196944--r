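#' @import methods
#' @importFrom BiocGenerics start end width strand sort
#' @importFrom S4Vectors DataFrame metadata mcols mcols<- queryHits
#'   subjectHits
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames findOverlaps countOverlaps
#'   reduce
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowRanges rowData rowData<- colData
#' @importFrom stats quantile p.adjust dhyper rgeom runif rbeta rbinom
#'   rpois setNames
NULL

.SYNC_BASES <- c("A", "T", "C", "G", "N", "del")
.ACGT <- c("A", "C", "G", "T")

#' PoolCounts: per-site, per-pool nucleotide counts
#'
#' The central substrate of the pipeline: for every genomic site, the number
#' of reads supporting each nucleotide (A, T, C, G, N and deletions,
#' following the sync-format column order) in each sequenced pool.
#' Implemented as a \linkS4class{RangedSummarizedExperiment} with one assay
#' per nucleotide class (sites x pools integer matrices). Pool roles
#' (\code{"domestic"} or \code{"wild"}) live in \code{colData(x)$role};
#' the reference base at each site in \code{rowData(x)$ref}.
#'
#' N and deletion counts are carried through I/O but never form alleles:
#' downstream SNP calling uses A/C/G/T only.
#'
#' @seealso \code{\link{readSync}}, \code{\link{callCandidates}},
#'   \code{\link{simulateCounts}}
#' @exportClass PoolCounts
setClass("PoolCounts", contains = "RangedSummarizedExperiment")

setValidity("PoolCounts", function(object) {
    msg <- character()
    if (!all(.SYNC_BASES %in% names(assays(object))))
        msg <- c(msg, sprintf("assays must include %s",
                              paste(.SYNC_BASES, collapse = ", ")))
    if (!"role" %in% names(colData(object)))
        msg <- c(msg, "colData must carry a 'role' column")
    else if (!all(colData(object)$role %in% c("domestic", "wild")))
        msg <- c(msg, "pool roles must be 'domestic' or 'wild'")
    if (!"ref" %in% names(rowData(object)))
        msg <- c(msg, "rowData must carry a 'ref' column")
    for (b in intersect(.SYNC_BASES, names(assays(object)))) {
        a <- assay(object, b)
        if (any(a < 0)) msg <- c(msg, sprintf("negative counts in assay '%s'", b))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a PoolCounts object
#'
#' @param chrom character vector of chromosome/scaffold names.
#' @param pos integer vector of 1-based site positions.
#' @param ref reference base at each site (A, C, G, T or N).
#' @param counts sites x pools x 6 integer array, nucleotide classes ordered
#'   A, T, C, G, N, deletion (sync column order).
#' @param roles character vector, one of \code{"domestic"}/\code{"wild"} per
#'   pool.
#' @param poolNames optional pool names; defaults to \code{pool1, pool2, ...}.
#' @return A \linkS4class{PoolCounts} object.
#' @examples
#' cnt <- array(0L, c(2, 2, 6))
#' cnt[, , 1] <- 10L  # all-A sites
#' pc <- PoolCounts(chrom = c("chr1", "chr1"), pos = c(100L, 200L),
#'                  ref = c("A", "A"), counts = cnt,
#'                  roles = c("domestic", "wild"))
#' siteDepth(pc)
#' @export
PoolCounts <- function(chrom, pos, ref, counts, roles,
                       poolNames = paste0("pool", seq_along(roles))) {
    stopifnot(length(chrom) == length(pos), length(ref) == length(pos),
              length(dim(counts)) == 3L, dim(counts)[3] == 6L,
              dim(counts)[1] == length(pos), dim(counts)[2] == length(roles))
    asy <- lapply(seq_len(6L), function(k) {
        m <- matrix(as.integer(counts[, , k]), nrow = length(pos),
                    dimnames = list(NULL, poolNames))
        m
    })
    names(asy) <- .SYNC_BASES
    rr <- GRanges(chrom, IRanges(pos, width = 1L))
    mcols(rr)$ref <- as.character(ref)
    se <- SummarizedExperiment(
        assays = asy, rowRanges = rr,
        colData = DataFrame(role = as.character(roles), row.names = poolNames))
    new("PoolCounts", se)
}

#' SnpCatalog: biallelic SNP catalogue with per-pool allele read counts
#'
#' Candidate or filtered SNPs as a \linkS4class{RangedSummarizedExperiment}
#' with assays \code{majorCount} and \code{minorCount} (sites x pools reads,
#' oriented by the scope in which the catalogue was called) and per-SNP
#' metadata in \code{rowData}: \code{majorAllele}, \code{minorAllele},
#' \code{thirdCount} (reads supporting the best non-major/minor base, used
#' for biallelic enforcement), \code{totalDepth} (all A/C/G/T reads over the
#' in-scope pools) and \code{maf} (minor allele read fraction, in
#' \eqn{[0, 0.5]}). Differentiation testing appends \code{p}, \code{q} and
#' \code{category} columns.
#'
#' @seealso \code{\link{callCandidates}}, \code{\link{findSignificant}}
#' @exportClass SnpCatalog
setClass("SnpCatalog", contains = "RangedSummarizedExperiment")

setValidity("SnpCatalog", function(object) {
    msg <- character()
    need <- c("majorCount", "minorCount")
    if (!all(need %in% names(assays(object))))
        msg <- c(msg, "assays must include majorCount and minorCount")
    rd <- rowData(object)
    for (col in c("majorAllele", "minorAllele", "totalDepth", "maf"))
        if (!col %in% names(rd)) msg <- c(msg, sprintf("rowData lacks '%s'", col))
    if (all(c("majorAllele", "minorAllele") %in% names(rd)) &&
        nrow(object) > 0 && any(rd$majorAllele == rd$minorAllele))
        msg <- c(msg, "major and minor allele must differ")
    if ("maf" %in% names(rd) && nrow(object) > 0 &&
        (any(rd$maf < 0) || any(rd$maf > 0.5 + 1e-12)))
        msg <- c(msg, "maf must lie in [0, 0.5]")
    if (length(msg)) msg else TRUE
})

#' FilterCriteria: the three-factor SNP quality filter
#'
#' Holds one combination of the three filtering factors: minimum total read
#' depth, maximum total read depth (either an absolute read count or a
#' quantile specification such as \code{"top2\%"}, meaning the 98th
#' percentile of site depths), and minimum minor allele read count.
#'
#' @slot minDepth minimum total depth (reads).
#' @slot maxDepth numeric read count, or \code{NA} when quantile-specified.
#' @slot maxDepthQuantile top fraction to exclude (e.g. 0.02), or \code{NA}.
#' @slot minMinor minimum summed minor allele read count.
#' @seealso \code{\link{filterCriteria}}, \code{\link{applyFilter}}
#' @exportClass FilterCriteria
setClass("FilterCriteria",
         representation(minDepth = "numeric", maxDepth = "numeric",
                        maxDepthQuantile = "numeric", minMinor = "numeric"))

setValidity("FilterCriteria", function(object) {
    msg <- character()
    if (object@minDepth < 1) msg <- c(msg, "minDepth must be >= 1")
    if (object@minMinor < 1) msg <- c(msg, "minMinor must be >= 1")
    if (is.na(object@maxDepth) && is.na(object@maxDepthQuantile))
        msg <- c(msg, "one of maxDepth / maxDepthQuantile must be set")
    if (!is.na(object@maxDepth) && object@maxDepth <= object@minDepth)
        msg <- c(msg, "maxDepth must exceed minDepth")
    if (!is.na(object@maxDepthQuantile) &&
        (object@maxDepthQuantile <= 0 || object@maxDepthQuantile >= 1))
        msg <- c(msg, "maxDepthQuantile must lie in (0, 1)")
    if (length(msg)) msg else TRUE
})

#' Create a SNP filter criteria set
#'
#' @param minDepth minimum total read depth across in-scope pools.
#' @param maxDepth maximum total depth: a number, or a string of the form
#'   \code{"topQ\%"} (e.g. \code{"top2\%"}) excluding the deepest Q\% of
#'   sites; the threshold is then resolved against the observed site-depth
#'   distribution when the filter is applied.
#' @param minMinor minimum summed minor allele read count.
#' @return A \linkS4class{FilterCriteria} object.
#' @examples
#' filterCriteria(30, 300, 5)
#' filterCriteria(20, "top2%", 2)
#' @export
filterCriteria <- function(minDepth, maxDepth, minMinor) {
    q <- NA_real_
    md <- NA_real_
    if (is.character(maxDepth)) {
        m <- regmatches(maxDepth,
                        regexec("^top([0-9.]+)%$", maxDepth))[[1]]
        if (length(m) != 2L)
            stop("maxDepth string must look like 'top2%', got: ", maxDepth)
        q <- as.numeric(m[2]) / 100
    } else {
        md <- as.numeric(maxDepth)
    }
    new("FilterCriteria", minDepth = as.numeric(minDepth), maxDepth = md,
        maxDepthQuantile = q, minMinor = as.numeric(minMinor))
}

setMethod("show", "FilterCriteria", function(object) {
    mx <- if (is.na(object@maxDepth))
        sprintf("top%g%% excluded", 100 * object@maxDepthQuantile)
    else format(object@maxDepth)
    cat(sprintf(
        "FilterCriteria: min depth %g, max depth %s, min minor count %g\n",
        object@minDepth, mx, object@minMinor))
})

setMethod("show", "PoolCounts", function(object) {
    cat(sprintf("PoolCounts: %d sites, %d pools (%d domestic, %d wild)\n",
                nrow(object), ncol(object),
                sum(colData(object)$role == "domestic"),
                sum(colData(object)$role == "wild")))
    callNextMethod()
})

setMethod("show", "SnpCatalog", function(object) {
    extra <- intersect(c("p", "q", "category"), names(rowData(object)))
    cat(sprintf("SnpCatalog: %d SNPs, %d pools%s\n", nrow(object), ncol(object),
                if (length(extra))
                    paste0(" [", paste(extra, collapse = ", "), "]")
                else ""))
    callNextMethod()
})
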