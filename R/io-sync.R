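#' Read per-pool nucleotide counts in sync format
#'
#' The sync format (popularised by Pool-seq SNP-calling tools) is a
#' tab-separated table with one genomic site per line: chromosome, 1-based
#' position, reference base, then one \code{A:T:C:G:N:del} colon-separated
#' count string per pool. Positions must be strictly increasing within each
#' chromosome.
#'
#' @param path path to an uncompressed sync file.
#' @param nPools expected number of pool columns.
#' @param roles pool roles (\code{"domestic"}/\code{"wild"}), either a
#'   character vector of length \code{nPools} or a spec string like
#'   \code{"domestic=1,2,3,4;wild=5"}. Defaults to all-domestic.
#' @return a \linkS4class{PoolCounts} object.
#' @examples
#' tf <- tempfile(fileext = ".sync")
#' writeLines("chr1\t100\tA\t10:2:0:0:0:0\t12:0:0:0:0:0", tf)
#' readSync(tf, nPools = 2, roles = c("domestic", "wild"))
#' @export
readSync <- function(path, nPools, roles = rep("domestic", nPools)) {
    if (is.character(roles) && length(roles) == 1L && grepl("=", roles))
        roles <- parsePoolSpec(roles, nPools)
    stopifnot(length(roles) == nPools)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) {
        return(PoolCounts(character(), integer(), character(),
                          array(0L, c(0L, nPools, 6L)), roles))
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(nf != 3L + nPools)
    if (length(bad))
        stop(sprintf(
            "sync line %d has %d fields; expected %d (3 + %d pools)",
            bad[1L], nf[bad[1L]], 3L + nPools, nPools))
    m <- matrix(unlist(fields), ncol = 3L + nPools, byrow = TRUE)
    chrom <- m[, 1L]
    pos <- suppressWarnings(as.integer(m[, 2L]))
    bad <- which(is.na(pos) | pos < 1L)
    if (length(bad))
        stop("sync line ", bad[1L], ": position must be a positive integer")
    nl <- length(pos)
    if (nl > 1L) {
        same <- chrom[-1L] == chrom[-nl]
        bad <- which(same & pos[-1L] <= pos[-nl])
        if (length(bad))
            stop("sync line ", bad[1L] + 1L,
                 ": positions must be strictly increasing within a chromosome")
    }
    blocks <- rle(chrom)$values
    if (anyDuplicated(blocks))
        stop("sync chromosomes are interleaved: ",
             blocks[duplicated(blocks)][1L])
    cstr <- m[, -(1:3), drop = FALSE]
    okc <- grepl("^[0-9]+(:[0-9]+){5}$", cstr)
    if (!all(okc)) {
        i <- which(!okc)[1L]
        stop("sync line ", (i - 1L) %% nrow(m) + 1L,
             ": malformed count string '", cstr[i], "'")
    }
    cnt <- array(as.integer(unlist(strsplit(t(cstr), ":", fixed = TRUE))),
                 dim = c(6L, nPools, nrow(m)))
    counts <- aperm(cnt, c(3L, 2L, 1L))
    PoolCounts(chrom, pos, m[, 3L], counts, roles)
}

#' Parse a pool-role specification string
#'
#' @param spec string of the form \code{"domestic=1,2,3,4;wild=5"} mapping
#'   1-based sync pool columns to roles.
#' @param nPools total number of pools; every pool must be assigned.
#' @return character vector of roles of length \code{nPools}.
#' @examples
#' parsePoolSpec("domestic=1,2,3,4;wild=5", 5)
#' @export
parsePoolSpec <- function(spec, nPools) {
    roles <- rep(NA_character_, nPools)
    for (part in strsplit(spec, ";", fixed = TRUE)[[1L]]) {
        kv <- strsplit(part, "=", fixed = TRUE)[[1L]]
        if (length(kv) != 2L || !kv[1L] %in% c("domestic", "wild"))
            stop("bad pool spec component: ", part)
        idx <- as.integer(strsplit(kv[2L], ",", fixed = TRUE)[[1L]])
        if (any(is.na(idx)) || any(idx < 1L) || any(idx > nPools))
            stop("pool indices out of range in: ", part)
        roles[idx] <- kv[1L]
    }
    if (any(is.na(roles)))
        stop("pool spec leaves pools unassigned: ",
             paste(which(is.na(roles)), collapse = ", "))
    roles
}

#' Write per-pool counts to sync format
#'
#' Inverse of \code{\link{readSync}}; \code{readSync(writeSync(x))}
#' reproduces \code{x} exactly.
#'
#' @param x a \linkS4class{PoolCounts} object.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeSync <- function(x, path) {
    n <- nrow(x)
    if (n == 0L) {
        writeLines(character(), path)
        return(invisible(path))
    }
    pools <- vapply(seq_len(ncol(x)), function(j) {
        cols <- lapply(.SYNC_BASES, function(b) assay(x, b)[, j])
        do.call(paste, c(cols, sep = ":"))
    }, character(n))
    if (n == 1L) pools <- matrix(pools, nrow = 1L)
    body <- do.call(paste, c(list(as.character(seqnames(rowRanges(x))),
                                  start(rowRanges(x)),
                                  rowData(x)$ref),
                             lapply(seq_len(ncol(pools)),
                                    function(j) pools[, j]),
                             sep = "\t"))
    writeLines(body, path)
    invisible(path)
}
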