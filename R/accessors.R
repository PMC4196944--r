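#' Pool role accessors
#'
#' @param x a \linkS4class{PoolCounts} or \linkS4class{SnpCatalog} object.
#' @return \code{poolRoles}: character vector of roles; \code{domesticPools}
#'   and \code{wildPool}: integer column indices.
#' @examples
#' pc <- simulateCounts(simulateFrequencies(simulationConfig(
#'     genome = list(chr1 = 1e5), seed = 1)),
#'     simulationConfig(genome = list(chr1 = 1e5), seed = 1))
#' poolRoles(pc)
#' domesticPools(pc)
#' @export
poolRoles <- function(x) as.character(colData(x)$role)

#' @rdname poolRoles
#' @export
domesticPools <- function(x) which(poolRoles(x) == "domestic")

#' @rdname poolRoles
#' @export
wildPool <- function(x) {
    w <- which(poolRoles(x) == "wild")
    if (length(w) == 0L) stop("no pool is configured with the 'wild' role")
    w
}

#' Total A/C/G/T read depth per site
#'
#' Depth excludes N and deletion counts, which never form alleles.
#'
#' @param x a \linkS4class{PoolCounts} object.
#' @param pools column indices to sum over; default all pools.
#' @return integer vector of summed depths, one per site.
#' @export
siteDepth <- function(x, pools = seq_len(ncol(x))) {
    d <- 0L
    for (b in .ACGT)
        d <- d + rowSums(assay(x, b)[, pools, drop = FALSE])
    as.integer(d)
}

#' Per-SNP metadata accessors
#'
#' @param x a \linkS4class{SnpCatalog}.
#' @return \code{majorAllele}/\code{minorAllele}: character vectors;
#'   \code{maf}: numeric minor allele read fractions; \code{totalDepth}:
#'   integer depths; \code{majorCounts}/\code{minorCounts}: sites x pools
#'   read matrices.
#' @export
majorAllele <- function(x) rowData(x)$majorAllele

#' @rdname majorAllele
#' @export
minorAllele <- function(x) rowData(x)$minorAllele

#' @rdname majorAllele
#' @export
maf <- function(x) rowData(x)$maf

#' @rdname majorAllele
#' @export
totalDepth <- function(x) rowData(x)$totalDepth

#' @rdname majorAllele
#' @export
majorCounts <- function(x) assay(x, "majorCount")

#' @rdname majorAllele
#' @export
minorCounts <- function(x) assay(x, "minorCount")
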