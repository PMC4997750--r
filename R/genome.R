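#' Construct a GenomeSpec
#'
#' @param chroms ordered chromosome names.
#' @param lengths chromosome lengths in bp.
#' @param centromeres centromere positions in bp (strictly inside each
#'   chromosome); they split each chromosome into p and q arms.
#' @return a [GenomeSpec-class].
#' @examples
#' gs <- GenomeSpec(c("1", "2"), c(60e6, 40e6), c(25e6, 15e6))
#' chromLengths(gs)
#' @export
GenomeSpec <- function(chroms, lengths, centromeres) {
  new("GenomeSpec",
    chroms = as.character(chroms),
    lengths = as.numeric(lengths),
    centromeres = as.numeric(centromeres)
  )
}

#' Load a genome specification from a TSV file
#'
#' Expects a tab-separated file with header columns `chrom`, `length`,
#' `centromere`.
#'
#' @param path file path.
#' @return a [GenomeSpec-class].
#' @export
loadGenome <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  need <- c("chrom", "length", "centromere")
  if (!all(need %in% colnames(tab)))
    stop("genome file must have columns: ", paste(need, collapse = ", "))
  GenomeSpec(tab$chrom, tab$length, tab$centromere)
}

#' The default human-like genome fixture
#'
#' A 23-sequence genome (22 autosomes + X) with hg19-like chromosome lengths
#' and approximate centromere positions, shipped as an editable TSV under
#' `inst/extdata/`. It fixes arm boundaries for arm-level event simulation
#' and segment annotation; it makes no claim about any particular sample's
#' reference build.
#'
#' @return a [GenomeSpec-class].
#' @examples
#' defaultGenome()
#' @export
defaultGenome <- function() {
  loadGenome(system.file("extdata", "genome_hg19like.tsv",
                         package = "cfScreen", mustWork = TRUE))
}

#' Chromosome-arm boundaries of a genome
#'
#' Splits every chromosome at its centromere into a p arm `[0, centromere)`
#' and a q arm `[centromere, length)` (0-based half-open bp).
#'
#' @param genome a [GenomeSpec-class].
#' @return a data.frame with columns `arm` (e.g. `"3q"`), `chrom`, `start`,
#'   `end`.
#' @examples
#' head(armBounds(defaultGenome()))
#' @export
armBounds <- function(genome) {
  stopifnot(is(genome, "GenomeSpec"))
  data.frame(
    arm = c(paste0(genome@chroms, "p"), paste0(genome@chroms, "q")),
    chrom = rep(genome@chroms, 2L),
    start = c(rep(0, length(genome@chroms)), genome@centromeres),
    end = c(genome@centromeres, genome@lengths),
    stringsAsFactors = FALSE
  )[order(rep(seq_along(genome@chroms), 2L)), ]
}

#' Arm boundaries as GRanges
#' @noRd
.armRanges <- function(genome) {
  ab <- armBounds(genome)
  gr <- GenomicRanges::GRanges(ab$chrom, IRanges::IRanges(ab$start + 1L, ab$end))
  S4Vectors::mcols(gr)$arm <- ab$arm
  gr
}

#' Deterministic GC model of the genome fixture
#'
#' GC content per position used when tiling a default grid: a smooth,
#' deterministic function of (chromosome index, position) centered on 0.41
#' with isochore-like undulation, clipped to [0.30, 0.60]. Deterministic so
#' that grids are reproducible without a sequence file.
#' @noRd
.fixtureGC <- function(chromIdx, midpoint) {
  gc <- 0.41 +
    0.06 * sin(midpoint / 8e6 + chromIdx * 0.7) +
    0.02 * cos(midpoint / 2.3e7 + chromIdx * 1.3)
  pmin(pmax(gc, 0.30), 0.60)
}
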