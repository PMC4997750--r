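## BinGrid construction and on-disk format.
## On-disk coordinates are 0-based half-open; the in-memory GRanges follows
## the Bioconductor 1-based closed convention (start0 + 1, end0).

#' Construct a BinGrid from 0-based half-open coordinates
#'
#' @param chrom chromosome per bin.
#' @param start,end 0-based half-open coordinates in bp.
#' @param gc GC fraction per bin, in `[0,1]`.
#' @param usable logical usability flag per bin (default all `TRUE`).
#' @param binSize nominal bin size in bp (default: the modal bin width).
#' @return a [BinGrid-class].
#' @examples
#' BinGrid(c("1", "1"), c(0, 1e6), c(1e6, 2e6), gc = c(0.4, 0.45))
#' @export
BinGrid <- function(chrom, start, end, gc, usable = NULL, binSize = NULL) {
  if (any(end <= start))
    stop("bins must have end > start (0-based half-open)")
  if (is.null(usable)) usable <- rep(TRUE, length(chrom))
  if (is.null(binSize)) {
    w <- end - start
    binSize <- as.numeric(names(sort(table(w), decreasing = TRUE))[1L])
  }
  gr <- GenomicRanges::GRanges(
    as.character(chrom),
    IRanges::IRanges(start = start + 1, end = end)
  )
  S4Vectors::mcols(gr)$gc <- as.numeric(gc)
  S4Vectors::mcols(gr)$usable <- as.logical(usable)
  new("BinGrid", bins = gr, binSize = as.numeric(binSize))
}

#' Number of bins in a grid
#' @param x a [BinGrid-class].
#' @return integer bin count.
#' @export
nBins <- function(x) length(x@bins)

## internal logical masks over grid bins
.gridChrom <- function(grid) as.character(GenomicRanges::seqnames(grid@bins))
.gridStart0 <- function(grid) GenomicRanges::start(grid@bins) - 1
.gridEnd0 <- function(grid) GenomicRanges::end(grid@bins)
.gridGC <- function(grid) S4Vectors::mcols(grid@bins)$gc

#' @noRd
usableBins <- function(grid) S4Vectors::mcols(grid@bins)$usable

#' @noRd
autosomalBins <- function(grid) .gridChrom(grid) != "X"

#' @noRd
autosomalUsable <- function(grid) usableBins(grid) & autosomalBins(grid)

#' Tile a genome into a constant-size bin grid
#'
#' Tiles each chromosome left to right with `binSize` bins. The trailing
#' partial bin of a chromosome is kept, and flagged unusable when shorter
#' than half the bin size. GC per bin comes from the deterministic fixture
#' GC model of the genome, so identical inputs always give an identical
#' grid.
#'
#' @param genome a [GenomeSpec-class].
#' @param binSize bin size in bp (>= 100 kb; default 1 Mb).
#' @return a [BinGrid-class].
#' @examples
#' grid <- makeDefaultGrid(defaultGenome(), 1e6)
#' nBins(grid)
#' @export
makeDefaultGrid <- function(genome, binSize = 1e6) {
  stopifnot(is(genome, "GenomeSpec"))
  if (length(binSize) != 1L || binSize <= 0)
    stop("binSize must be a single positive number")
  if (binSize < 1e5)
    stop("binSize must be at least 100 kb")
  chroms <- genome@chroms
  lens <- genome@lengths
  parts <- lapply(seq_along(chroms), function(ci) {
    len <- lens[ci]
    starts <- seq(0, len - 1, by = binSize)
    ends <- pmin(starts + binSize, len)
    width <- ends - starts
    mids <- (starts + ends) / 2
    data.frame(
      chrom = chroms[ci], start = starts, end = ends,
      gc = .fixtureGC(ci, mids),
      usable = width >= binSize / 2,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, parts)
  BinGrid(tab$chrom, tab$start, tab$end, tab$gc, tab$usable, binSize = binSize)
}

#' Read a bin grid from a TSV file
#'
#' Expects tab-separated columns `chrom`, `start`, `end`, `gc` (0-based
#' half-open bp) and optionally `usable`; rejects unsorted or overlapping
#' bins.
#'
#' @param path file path.
#' @return a validated [BinGrid-class].
#' @seealso [writeBinGrid()]
#' @export
loadBinGrid <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- tryCatch(
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      colClasses = c(chrom = "character")),
    error = function(e) stop("malformed bin grid file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  need <- c("chrom", "start", "end", "gc")
  if (!all(need %in% colnames(tab)))
    stop("bin grid file must have columns: ", paste(need, collapse = ", "))
  bad <- which(!is.finite(tab$start) | !is.finite(tab$end) | !is.finite(tab$gc))
  if (length(bad))
    stop("malformed bin grid line ", bad[1L] + 1L, " in ", path)
  if (any(tab$end <= tab$start)) {
    i <- which(tab$end <= tab$start)[1L]
    stop("bin grid validation: end <= start at line ", i + 1L)
  }
  usable <- if ("usable" %in% colnames(tab)) as.logical(tab$usable)
            else rep(TRUE, nrow(tab))
  grid <- BinGrid(tab$chrom, tab$start, tab$end, tab$gc, usable)
  methods::validObject(grid)
  grid
}

#' Write a bin grid to a TSV file
#'
#' Inverse of [loadBinGrid()]; coordinates written 0-based half-open.
#'
#' @param grid a [BinGrid-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeBinGrid <- function(grid, path) {
  stopifnot(is(grid, "BinGrid"))
  tab <- data.frame(
    chrom = .gridChrom(grid),
    start = format(.gridStart0(grid), scientific = FALSE, trim = TRUE),
    end = format(.gridEnd0(grid), scientific = FALSE, trim = TRUE),
    gc = .gridGC(grid),
    usable = usableBins(grid)
  )
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
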