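#' Read a FASTQ file (Sanger Phred+33)
#'
#' Parses plain 4-line-record FASTQ. Malformed records — a header not
#' starting with \code{@}, a missing \code{+} separator, a quality string
#' whose length differs from the sequence, quality characters outside the
#' Sanger range (Phred 0--93), or a truncated trailing record — raise an
#' error naming the offending line.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return a \link[Biostrings]{QualityScaledDNAStringSet} named by read id
#'   (the header up to the first whitespace); empty for an empty file.
#' @examples
#' fq <- system.file("extdata", "example.fastq", package = "poolsweep")
#' readFastq(fq)
#' @export
readFastq <- function(path) {
    lines <- readLines(path)
    n <- length(lines)
    if (n == 0L)
        return(Biostrings::QualityScaledDNAStringSet(
            Biostrings::DNAStringSet(),
            Biostrings::PhredQuality(character())))
    if (n %% 4L != 0L)
        stop("truncated FASTQ record starting at line ", (n %/% 4L) * 4L + 1L)
    hdr <- lines[seq(1L, n, by = 4L)]
    seqs <- lines[seq(2L, n, by = 4L)]
    sep <- lines[seq(3L, n, by = 4L)]
    qual <- lines[seq(4L, n, by = 4L)]
    bad <- which(!startsWith(hdr, "@"))
    if (length(bad))
        stop("FASTQ header must start with '@' at line ", (bad[1L] - 1L) * 4L + 1L)
    bad <- which(!startsWith(sep, "+"))
    if (length(bad))
        stop("FASTQ separator must start with '+' at line ", (bad[1L] - 1L) * 4L + 3L)
    bad <- which(nchar(qual) != nchar(seqs))
    if (length(bad))
        stop("quality length differs from sequence length at line ",
             (bad[1L] - 1L) * 4L + 4L)
    qraw <- lapply(qual, function(s) as.integer(charToRaw(s)))
    bad <- which(vapply(qraw, function(r)
        length(r) > 0 && (min(r) < 33L || max(r) > 126L), logical(1)))
    if (length(bad))
        stop("quality characters outside Sanger Phred+33 range at line ",
             (bad[1L] - 1L) * 4L + 4L)
    ids <- sub("\\s.*$", "", substring(hdr, 2L))
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- ids
    Biostrings::QualityScaledDNAStringSet(dna, Biostrings::PhredQuality(qual))
}

#' Write reads to FASTQ (Sanger Phred+33)
#'
#' @param reads a \link[Biostrings]{QualityScaledDNAStringSet}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeFastq <- function(reads, path) {
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(reads))
    out <- character(4L * length(reads))
    if (length(reads)) {
        out[seq(1L, length(out), by = 4L)] <- paste0("@", ids)
        out[seq(2L, length(out), by = 4L)] <- as.character(reads)
        out[seq(3L, length(out), by = 4L)] <- "+"
        out[seq(4L, length(out), by = 4L)] <-
            as.character(Biostrings::quality(reads))
    }
    writeLines(out, path)
    invisible(path)
}
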