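.fmt1 <- function(x) formatC(x, format = "f", digits = 1)
.fmt2 <- function(x) formatC(x, format = "f", digits = 2)
.fmt3 <- function(x) formatC(x, format = "f", digits = 3)

#' Write pipeline result tables
#'
#' Tab-separated reports with a header line. Numeric formatting: Hp to 3
#' decimals, transformed Hp to 2 decimals, percentages and MAF-percentages
#' to 1 decimal; p/q values in scientific notation. The \code{"region"}
#' kind emits BED-convention intervals (0-based half-open) so sweep calls
#' load directly into genome browsers.
#'
#' @param records the records to write: a \linkS4class{SnpCatalog} for kinds
#'   \code{"snp"}/\code{"significant"}, the \link[GenomicRanges]{GRanges}
#'   returned by \code{\link{windowHp}} for \code{"window"}, the GRanges
#'   from \code{\link{callSweeps}} for \code{"region"}, or the data.frame
#'   from \code{\link{criteriaGrid}} for \code{"grid"}.
#' @param path output file path.
#' @param kind which report shape to write.
#' @return invisibly, \code{path}.
#' @export
writeTables <- function(records, path,
                        kind = c("snp", "significant", "window",
                                 "region", "grid")) {
    kind <- match.arg(kind)
    df <- switch(kind,
        snp = .snpTable(records, significant = FALSE),
        significant = .snpTable(records, significant = TRUE),
        window = .windowTable(records),
        region = .regionTable(records),
        grid = .gridTable(records))
    lines <- paste0("#", paste(names(df), collapse = "\t"))
    if (nrow(df))
        lines <- c(lines, do.call(paste, c(unname(as.list(df)), sep = "\t")))
    writeLines(lines, path)
    invisible(path)
}

.snpTable <- function(x, significant) {
    stopifnot(is(x, "SnpCatalog"))
    rd <- rowData(x)
    df <- data.frame(
        chrom = as.character(seqnames(rowRanges(x))),
        pos = start(rowRanges(x)),
        major = rd$majorAllele, minor = rd$minorAllele,
        depth = rd$totalDepth, maf = .fmt3(rd$maf))
    if (significant) {
        df$p <- formatC(rd$p, format = "e", digits = 3)
        df$q <- formatC(rd$q, format = "e", digits = 3)
        if ("category" %in% names(rd)) df$category <- as.character(rd$category)
    }
    df
}

.windowTable <- function(w) {
    stopifnot(is(w, "GRanges"))
    data.frame(
        chrom = as.character(seqnames(w)),
        start = start(w), end = end(w),
        nSnps = mcols(w)$nSnps,
        sumMaj = mcols(w)$sumMaj, sumMin = mcols(w)$sumMin,
        hp = .fmt3(mcols(w)$hp),
        hpTransformed = .fmt2(mcols(w)$hpTransformed))
}

.regionTable <- function(r) {
    stopifnot(is(r, "GRanges"))
    genes <- if ("genes" %in% names(mcols(r)))
        vapply(mcols(r)$genes, function(g)
            if (length(g)) paste(g, collapse = ",") else ".", character(1))
    else rep(".", length(r))
    data.frame(
        chrom = as.character(seqnames(r)),
        start = start(r) - 1L,  # BED 0-based half-open
        end = end(r),
        name = paste0("sweep_", seq_len(length(r))),
        score = .fmt2(mcols(r)$maxTransformed),
        strand = ".",
        minHp = .fmt3(mcols(r)$minHp),
        nWindows = lengths(mcols(r)$windowIds),
        genes = genes)
}

.gridTable <- function(g) {
    stopifnot(is.data.frame(g))
    data.frame(
        minDepth = g$minDepth, maxDepth = g$maxDepth,
        minMinor = g$minMinor, resolvedMaxDepth = g$resolvedMaxDepth,
        pctReadsIncluded = .fmt1(g$pctReadsIncluded),
        nSnps = g$nSnps)
}
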