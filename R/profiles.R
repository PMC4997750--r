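#' Construct a SampleProfile from raw bin counts
#'
#' @param sampleId sample identifier.
#' @param grid the [BinGrid-class] the counts are aligned to.
#' @param counts non-negative integer counts, one per grid bin.
#' @return an un-normalized [SampleProfile-class].
#' @seealso [normalizeCounts()], [gcCorrect()]
#' @export
SampleProfile <- function(sampleId, grid, counts) {
  stopifnot(is(grid, "BinGrid"))
  counts <- as.numeric(counts)
  if (length(counts) != nBins(grid))
    stop("counts length (", length(counts), ") does not match grid (",
         nBins(grid), " bins)")
  if (any(counts < 0, na.rm = TRUE)) stop("raw counts must be non-negative")
  new("SampleProfile",
    sampleId = as.character(sampleId), grid = grid, counts = counts,
    values = rep(NA_real_, length(counts)),
    totalReads = sum(counts[usableBins(grid)]),
    normalized = FALSE, gcCorrected = FALSE
  )
}

#' Read per-bin counts for one sample
#'
#' Reads a tab-separated count file (columns `chrom`, `start`, `end`, `gc`,
#' `count`; 0-based half-open coordinates) and attaches the counts to a
#' [BinGrid-class]. The file's bins must match the grid coordinates exactly,
#' in order. Normalized values are unset until [normalizeCounts()].
#'
#' @param path count file path.
#' @param grid the [BinGrid-class] to align to.
#' @param sampleId sample identifier; defaults to the file name without
#'   extension.
#' @return a [SampleProfile-class].
#' @seealso [writeBinCounts()]
#' @export
readBinCounts <- function(path, grid, sampleId = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  need <- c("chrom", "start", "end", "count")
  if (!all(need %in% colnames(tab)))
    stop("count file must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab) != nBins(grid))
    stop("count file has ", nrow(tab), " bins but grid has ", nBins(grid))
  mismatch <- which(tab$chrom != .gridChrom(grid) |
                    tab$start != .gridStart0(grid) |
                    tab$end != .gridEnd0(grid))
  if (length(mismatch)) {
    i <- mismatch[1L]
    stop(sprintf(
      "bin %d mismatches grid: file has %s:%d-%d, grid has %s:%d-%d",
      i, tab$chrom[i], tab$start[i], tab$end[i],
      .gridChrom(grid)[i], .gridStart0(grid)[i], .gridEnd0(grid)[i]
    ))
  }
  if (any(tab$count < 0))
    stop("negative count at bin ", which(tab$count < 0)[1L])
  SampleProfile(sampleId, grid, tab$count)
}

#' Write per-bin counts for one sample
#'
#' Inverse of [readBinCounts()]: tab-separated `chrom`, `start`, `end`,
#' `gc`, `count` with 0-based half-open coordinates.
#'
#' @param profile a [SampleProfile-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBinCounts <- function(profile, path) {
  stopifnot(is(profile, "SampleProfile"))
  grid <- profile@grid
  tab <- data.frame(
    chrom = .gridChrom(grid),
    start = format(.gridStart0(grid), scientific = FALSE, trim = TRUE),
    end = format(.gridEnd0(grid), scientific = FALSE, trim = TRUE),
    gc = .gridGC(grid),
    count = format(profile@counts, scientific = FALSE, trim = TRUE)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
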