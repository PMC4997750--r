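## Segment BED6+3 output: chrom, start, end, name (gain|loss), score
## (|mean windowed Z| capped at 1000), strand '.', then size_mb, arms and
## specificity class ('.' when not yet annotated). 0-based half-open.

#' Write called segments to a BED6+3 file
#'
#' @param segments `GRanges` from [callSegments()], optionally carrying
#'   `arms` and `class` metadata columns from [annotateSegments()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readSegments()]
#' @export
writeSegments <- function(segments, path) {
  mc <- S4Vectors::mcols(segments)
  arms <- if ("arms" %in% colnames(mc)) mc$arms else rep(".", length(segments))
  cls <- if ("class" %in% colnames(mc)) mc$class else rep(".", length(segments))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#chrom", "start", "end", "name", "score", "strand",
                   "size_mb", "arms", "class", sep = "\t"), con)
  if (length(segments)) {
    lines <- paste(
      as.character(GenomicRanges::seqnames(segments)),
      format(GenomicRanges::start(segments) - 1, scientific = FALSE, trim = TRUE),
      format(GenomicRanges::end(segments), scientific = FALSE, trim = TRUE),
      mc$direction,
      pmin(round(abs(mc$meanZ)), 1000),
      ".",
      format(mc$sizeMb, trim = TRUE),
      arms, cls,
      sep = "\t"
    )
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read segments back from a BED6+3 file
#'
#' Inverse of [writeSegments()] for coordinates, direction, size and
#' annotation columns (the mean windowed Z is recovered only at the
#' integer-score precision the BED score field carries).
#'
#' @param path BED file path.
#' @return a `GRanges` of segments.
#' @export
readSegments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(.emptySegments())
  tab <- utils::read.delim(text = lines, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = c(V1 = "character"))
  gr <- GenomicRanges::GRanges(tab$V1, IRanges::IRanges(tab$V2 + 1, tab$V3))
  S4Vectors::mcols(gr)$direction <- tab$V4
  S4Vectors::mcols(gr)$meanZ <- ifelse(tab$V4 == "loss", -tab$V5, tab$V5)
  S4Vectors::mcols(gr)$nBins <- NA_integer_
  S4Vectors::mcols(gr)$sizeMb <- tab$V7
  if (ncol(tab) >= 9) {
    S4Vectors::mcols(gr)$arms <- tab$V8
    S4Vectors::mcols(gr)$class <- tab$V9
  }
  gr
}
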