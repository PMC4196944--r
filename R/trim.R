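#' Convert a Phred quality score to an error probability
#'
#' The Phred scale defines the base-calling error probability as
#' \eqn{P = 10^{-Q/10}}; Q20 corresponds to a 1\% error rate.
#'
#' @param Q integer (or numeric) Phred scores, all \eqn{\ge 0}.
#' @return numeric error probabilities in \eqn{(0, 1]}.
#' @examples
#' phredToError(c(0, 10, 20, 40))
#' @export
phredToError <- function(Q) {
    if (any(Q < 0)) stop("Phred scores must be non-negative")
    10^(-Q / 10)
}

#' Trimming configuration
#'
#' @slot quality Phred threshold A of the running-sum trimmer; bases with
#'   \eqn{Q < A} contribute negatively.
#' @slot minLength minimum retained read length (bp) kept by
#'   \code{\link{qcFilter}}.
#' @slot dropN discard reads whose retained span contains an N.
#' @slot clamp clamp the running sum at zero when it goes negative
#'   (standard modified-Mott behaviour); \code{FALSE} uses the plain
#'   unclamped running sum.
#' @slot meanQuality optional whole-read mean-quality floor applied after
#'   trimming (\code{NA} disables it, the default).
#' @exportClass TrimConfig
setClass("TrimConfig",
         representation(quality = "numeric", minLength = "numeric",
                        dropN = "logical", clamp = "logical",
                        meanQuality = "numeric"))

setValidity("TrimConfig", function(object) {
    msg <- character()
    if (object@quality < 0) msg <- c(msg, "quality threshold must be >= 0")
    if (object@minLength < 1) msg <- c(msg, "minLength must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @param quality,minLength,dropN,clamp,meanQuality see the slot
#'   descriptions.
#' @return \code{trimConfig} returns a \linkS4class{TrimConfig}.
#' @examples
#' trimConfig()
#' @rdname TrimConfig-class
#' @export
trimConfig <- function(quality = 20, minLength = 30, dropN = TRUE,
                       clamp = TRUE, meanQuality = NA_real_) {
    new("TrimConfig", quality = quality, minLength = minLength,
        dropN = dropN, clamp = clamp, meanQuality = as.numeric(meanQuality))
}

setMethod("show", "TrimConfig", function(object) {
    cat(sprintf(
        "TrimConfig: quality %g, min length %g bp, dropN=%s, clamp=%s\n",
        object@quality, object@minLength, object@dropN, object@clamp))
})

## Clamped running sum via the prefix-minimum identity:
## s_k = x_k - min(0, min_{j<=k} x_j) with x = cumsum(v).
.runningSum <- function(v, clamp) {
    x <- cumsum(v)
    if (clamp) x - pmin(cummin(x), 0) else x
}

.mottSpan <- function(quals, A, clamp) {
    if (length(quals) == 0L) return(c(1L, 0L))
    v <- phredToError(A) - phredToError(quals)
    s <- .runningSum(v, clamp)
    pos <- which(s > 0)
    if (length(pos) == 0L) return(c(1L, 0L))
    i <- pos[1L]
    m <- max(s)
    # rightmost index attaining the maximum keeps zero-valued (Q == A) tails
    j <- max(which(s >= m - 1e-12))
    c(i, j)
}

#' Quality-trim reads by the modified-Mott running-sum algorithm
#'
#' Each base quality Q is converted to an error probability and compared
#' with the probability of the threshold quality A: the per-base value
#' \eqn{v = P(A) - P(Q)} is positive for bases better than A and negative
#' otherwise. A running sum of v is accumulated along the read (clamped at
#' zero when it goes negative, unless \code{clamp} is disabled) and the
#' retained region runs from the first position where the sum becomes
#' positive to the rightmost position attaining its maximum. Reads whose
#' sum never becomes positive are trimmed away entirely.
#'
#' @param reads a \link[Biostrings]{QualityScaledDNAStringSet}, e.g. from
#'   \code{\link{readFastq}}.
#' @param config a \linkS4class{TrimConfig}.
#' @return an \link[IRanges]{IRanges} of retained spans (1-based, closed;
#'   zero width when the whole read is discarded), one per read, named by
#'   read id.
#' @examples
#' rd <- readFastq(system.file("extdata", "example.fastq",
#'                             package = "poolsweep"))
#' mottTrim(rd)
#' @export
mottTrim <- function(reads, config = trimConfig()) {
    quals <- as(Biostrings::quality(reads), "IntegerList")
    spans <- vapply(quals, .mottSpan, integer(2L),
                    A = config@quality, clamp = config@clamp)
    IRanges(start = spans[1L, ], end = spans[2L, ], names = names(reads))
}

#' Trim and quality-filter a read set
#'
#' Applies \code{\link{mottTrim}}, then discards reads whose retained span
#' is shorter than \code{minLength} bp or (when \code{dropN}) contains an
#' ambiguous base. An optional mean-quality floor over the retained span
#' can be enabled via \code{meanQuality} in the configuration; it is off by
#' default, the running-sum threshold being the only quality filter.
#'
#' @inheritParams mottTrim
#' @param spans precomputed retained spans from \code{\link{mottTrim}};
#'   computed internally when \code{NULL}.
#' @return a list with \code{reads} (the trimmed, kept
#'   \link[Biostrings]{QualityScaledDNAStringSet}) and \code{summary}
#'   (data.frame: input count, kept count, kept fraction, mean retained
#'   length of kept reads).
#' @examples
#' rd <- readFastq(system.file("extdata", "example.fastq",
#'                             package = "poolsweep"))
#' qcFilter(rd)$summary
#' @export
qcFilter <- function(reads, config = trimConfig(), spans = NULL) {
    if (is.null(spans)) spans <- mottTrim(reads, config)
    stopifnot(length(spans) == length(reads))
    trimmed <- IRanges::narrow(reads, start = start(spans),
                               end = end(spans))
    keep <- width(spans) >= config@minLength
    if (config@dropN && any(keep)) {
        hasN <- Biostrings::letterFrequency(trimmed, "N")[, 1] > 0
        keep <- keep & !hasN
    }
    if (!is.na(config@meanQuality) && any(keep)) {
        mq <- vapply(as(Biostrings::quality(trimmed), "IntegerList"),
                     function(q) if (length(q)) mean(q) else 0, numeric(1))
        keep <- keep & mq >= config@meanQuality
    }
    kept <- trimmed[keep]
    summ <- data.frame(
        input = length(reads),
        kept = sum(keep),
        keptFraction = if (length(reads)) sum(keep) / length(reads) else NA_real_,
        meanRetainedLength = if (sum(keep)) mean(width(kept)) else NA_real_)
    list(reads = kept, summary = summ)
}
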