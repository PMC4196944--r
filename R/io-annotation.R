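## Normalise a feature GRanges to the internal form: metadata columns
## feature_id and is_coding. Accepts readAnnotation() output unchanged, or
## GFF-style columns (type + ID/Name, e.g. from makeAnnotation()).
.asFeatures <- function(gr) {
    md <- mcols(gr)
    if (all(c("feature_id", "is_coding") %in% names(md))) return(gr)
    id <- if ("Name" %in% names(md)) as.character(md$Name)
          else if ("ID" %in% names(md)) as.character(md$ID)
          else paste0("feature_", seq_along(gr))
    coding <- if ("type" %in% names(md))
        as.character(md$type) %in% c("CDS", "exon")
    else rep(TRUE, length(gr))
    out <- gr
    mcols(out) <- DataFrame(feature_id = id, is_coding = coding)
    out
}

#' Read gene/coding annotation from GFF3 or BED
#'
#' Coordinates are normalised to the 1-based closed GRanges convention
#' (rtracklayer converts BED's 0-based half-open intervals on import).
#' GFF3 \code{CDS} and \code{exon} features are flagged as coding; BED
#' intervals are treated as coding intervals (the typical input being a
#' coding-region BED).
#'
#' @param path annotation file path.
#' @param format \code{"gff3"} or \code{"bed"}; guessed from the file
#'   extension when missing.
#' @return a \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{feature_id} and \code{is_coding}. Strand is recorded but ignored
#'   by all downstream computations.
#' @examples
#' tf <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t300\tgeneA", tf)
#' readAnnotation(tf)
#' @export
readAnnotation <- function(path, format = c("guess", "gff3", "bed")) {
    format <- match.arg(format)
    if (format == "guess") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext, gff = , gff3 = "gff3", bed = "bed",
                         stop("cannot guess annotation format from '.",
                              ext, "'; pass format="))
    }
    gr <- if (format == "gff3")
        rtracklayer::import(path, format = "gff3")
    else
        rtracklayer::import(path, format = "bed")
    if (any(width(gr) < 1L))
        stop("annotation contains empty intervals (end <= start)")
    md <- mcols(gr)
    id <- if ("ID" %in% names(md) && !all(is.na(md$ID))) as.character(md$ID)
          else if ("Name" %in% names(md)) as.character(md$Name)
          else if ("name" %in% names(md)) as.character(md$name)
          else rep(NA_character_, length(gr))
    id[is.na(id) | !nzchar(id)] <-
        paste0("feature_", which(is.na(id) | !nzchar(id)))
    coding <- if (format == "gff3" && "type" %in% names(md))
        as.character(md$type) %in% c("CDS", "exon")
    else rep(TRUE, length(gr))
    out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                   strand = strand(gr))
    mcols(out)$feature_id <- id
    mcols(out)$is_coding <- coding
    out
}
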