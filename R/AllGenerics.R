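#' Accessors for cfScreen classes
#'
#' Small accessor generics so that slot access never appears in user code:
#' `sampleId()` returns a sample/subject identifier, `binRanges()` the
#' underlying `GRanges` of a grid, `rawCounts()` / `normValues()` the count
#' and normalized-value tracks of a profile, `catalogTable()` the catalog's
#' data.frame, and `truthEvents()` a truth profile's event table.
#'
#' @param x an object of the documented class.
#' @return the accessed component; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("binRanges", function(x) standardGeneric("binRanges"))

#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname accessors
#' @export
setGeneric("rawCounts", function(x) standardGeneric("rawCounts"))

#' @rdname accessors
#' @export
setGeneric("normValues", function(x) standardGeneric("normValues"))

#' @rdname accessors
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname accessors
#' @export
setGeneric("binGrid", function(x) standardGeneric("binGrid"))

#' @rdname accessors
#' @export
setGeneric("catalogTable", function(x) standardGeneric("catalogTable"))

#' @rdname accessors
#' @export
setGeneric("truthEvents", function(x) standardGeneric("truthEvents"))

#' @rdname accessors
#' @export
setGeneric("tumorFraction", function(x) standardGeneric("tumorFraction"))

#' @rdname accessors
#' @export
setGeneric("chromNames", function(x) standardGeneric("chromNames"))

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname accessors
#' @export
setGeneric("centromeres", function(x) standardGeneric("centromeres"))

#' @rdname accessors
#' @export
setGeneric("screenStatus", function(x) standardGeneric("screenStatus"))

#' @rdname accessors
#' @export
setGeneric("individualZ", function(x) standardGeneric("individualZ"))

#' @rdname accessors
#' @export
setGeneric("windowedZ", function(x) standardGeneric("windowedZ"))

## -- methods ----------------------------------------------------------------

#' @rdname accessors
setMethod("sampleId", "SampleProfile", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "ZProfile", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "ScreenCall", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "AneuploidyResult", function(x) x@sampleId)

#' @rdname accessors
setMethod("binRanges", "BinGrid", function(x) x@bins)
#' @rdname accessors
setMethod("binSize", "BinGrid", function(x) x@binSize)
#' @rdname accessors
setMethod("binGrid", "SampleProfile", function(x) x@grid)
#' @rdname accessors
setMethod("binGrid", "ZProfile", function(x) x@grid)
#' @rdname accessors
setMethod("binGrid", "ReferenceIndex", function(x) x@grid)

#' @rdname accessors
setMethod("rawCounts", "SampleProfile", function(x) x@counts)
#' @rdname accessors
setMethod("normValues", "SampleProfile", function(x) x@values)
#' @rdname accessors
setMethod("totalReads", "SampleProfile", function(x) x@totalReads)

#' @rdname accessors
setMethod("catalogTable", "CNVCatalog", function(x) x@table)
#' @rdname accessors
setMethod("truthEvents", "TruthProfile", function(x) x@events)
#' @rdname accessors
setMethod("tumorFraction", "TruthProfile", function(x) x@tumorFraction)

#' @rdname accessors
setMethod("chromNames", "GenomeSpec", function(x) x@chroms)
#' @rdname accessors
setMethod("chromLengths", "GenomeSpec", function(x) stats::setNames(x@lengths, x@chroms))
#' @rdname accessors
setMethod("centromeres", "GenomeSpec", function(x) stats::setNames(x@centromeres, x@chroms))

#' @rdname accessors
setMethod("screenStatus", "ScreenCall", function(x) x@status)
#' @rdname accessors
setMethod("screenStatus", "AneuploidyResult", function(x) x@status)

#' @rdname accessors
setMethod("individualZ", "ZProfile", function(x) x@z)
#' @rdname accessors
setMethod("windowedZ", "ZProfile", function(x) x@zWindowed)

## -- show methods -----------------------------------------------------------

setMethod("show", "GenomeSpec", function(object) {
  cat(sprintf(
    "GenomeSpec: %d chromosomes, %.2f Gb total\n",
    length(object@chroms), sum(object@lengths) / 1e9
  ))
})

setMethod("show", "BinGrid", function(object) {
  cat(sprintf(
    "BinGrid: %d bins of %s bp (%d usable) on %d chromosomes\n",
    length(object@bins), format(object@binSize, big.mark = ","),
    sum(S4Vectors::mcols(object@bins)$usable),
    length(unique(as.character(GenomicRanges::seqnames(object@bins))))
  ))
})

setMethod("show", "SampleProfile", function(object) {
  cat(sprintf(
    "SampleProfile '%s': %s reads over %d bins [%s%s]\n",
    object@sampleId, format(object@totalReads, big.mark = ","),
    length(object@counts),
    if (object@normalized) "normalized" else "raw",
    if (object@gcCorrected) ", GC-corrected" else ""
  ))
})

setMethod("show", "ReferenceIndex", function(object) {
  cat(sprintf(
    "ReferenceIndex: %d scored bins, k = %d, panel of %d samples%s\n",
    length(object@usableIdx), object@k, object@panelSize,
    if (object@excludeSameChrom) " (same-chromosome bins excluded)" else ""
  ))
})

setMethod("show", "ZProfile", function(object) {
  cat(sprintf(
    "ZProfile '%s': %d scored bins%s\n",
    object@sampleId, length(object@usableIdx),
    if (!is.na(object@window)) sprintf(", windowed (w = %d)", object@window)
    else " (individual only)"
  ))
})

setMethod("show", "CNVCatalog", function(object) {
  tab <- object@table
  cat(sprintf(
    "CNVCatalog: %d records (%d gains, %d losses)\n",
    nrow(tab), sum(tab$direction == "gain"), sum(tab$direction == "loss")
  ))
})

setMethod("show", "TruthProfile", function(object) {
  cat(sprintf(
    "TruthProfile: tumor fraction %.3f, %d events (%d arm-level, %d focal)\n",
    object@tumorFraction, nrow(object@events),
    sum(object@events$origin == "catalog"), sum(object@events$origin == "focal")
  ))
})

setMethod("show", "ScreenCall", function(object) {
  cat(sprintf(
    "ScreenCall '%s': %s (%d segments, %d >= %.1f Mb)\n",
    object@sampleId, object@status, length(object@segments),
    length(object@qualifying), object@minSizeMb
  ))
})

setMethod("show", "AneuploidyResult", function(object) {
  if (object@status == "no_call") {
    cat(sprintf("AneuploidyResult '%s': no_call (%s)\n", object@sampleId, object@reason))
  } else {
    cat(sprintf(
      "AneuploidyResult '%s': %s\n", object@sampleId,
      paste(sprintf("chr%s=%s", names(object@calls), object@calls), collapse = ", ")
    ))
  }
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    "SimParams: reads U[%.1fM, %.1fM], GC slope sd %.2f, NB dispersion %g\n",
    object@readsMin / 1e6, object@readsMax / 1e6, object@gcSlopeSd, object@dispersion
  ))
})
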