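#' Assemble a cohort screen report
#'
#' Combines per-subject screen calls, segment annotations and aneuploidy
#' results with cohort-level confusion counts and exact intervals into one
#' JSON-serializable structure. The aneuploidy block carries a note that
#' its no-call rule approximates, not reproduces, clinical pipeline QC.
#'
#' @param screenCalls list of [ScreenCall-class] objects.
#' @param manifest cohort manifest data.frame (`sample_id`, `group`,
#'   optionally `stage_label`).
#' @param annotatedSegments optional named list (by sample id) of annotated
#'   segment `GRanges` from [annotateSegments()].
#' @param aneuploidy optional list of [AneuploidyResult-class] objects.
#' @return a nested list with `subjects` and `cohort` blocks.
#' @seealso [writeReport()]
#' @export
screenReport <- function(screenCalls, manifest, annotatedSegments = NULL,
                         aneuploidy = NULL) {
  counts <- confusionTable(screenCalls, manifest)
  perf <- performanceReport(counts)
  aneuByid <- if (is.null(aneuploidy)) list() else
    stats::setNames(aneuploidy, vapply(aneuploidy, sampleId, character(1)))
  subjects <- lapply(screenCalls, function(call) {
    id <- sampleId(call)
    segs <- if (!is.null(annotatedSegments) && id %in% names(annotatedSegments))
      .segmentsToList(annotatedSegments[[id]]) else .segmentsToList(call@segments)
    aneu <- if (id %in% names(aneuByid)) {
      a <- aneuByid[[id]]
      if (screenStatus(a) == "no_call")
        list(status = "no_call", reason = a@reason)
      else list(status = "reported", calls = as.list(a@calls))
    } else NULL
    list(
      sample_id = id, screen_status = screenStatus(call),
      n_segments = length(call@segments),
      n_qualifying = length(call@qualifying),
      n_focal = countFocalAberrations(call@segments, call@minSizeMb),
      segments = segs, aneuploidy = aneu
    )
  })
  list(
    subjects = subjects,
    cohort = list(
      counts = counts[c("tp", "fn", "fp", "tn")],
      by_stage = counts$byStage,
      sensitivity = perf$sensitivity,
      specificity = perf$specificity
    ),
    notes = paste("aneuploidy no-call rule is a generic normalized-",
                  "chromosome-value approximation of clinical pipeline QC",
                  sep = "")
  )
}

.segmentsToList <- function(segments) {
  if (!length(segments)) return(list())
  mc <- S4Vectors::mcols(segments)
  lapply(seq_along(segments), function(i) {
    out <- list(
      chrom = as.character(GenomicRanges::seqnames(segments))[i],
      start = GenomicRanges::start(segments)[i] - 1,
      end = GenomicRanges::end(segments)[i],
      direction = mc$direction[i],
      mean_windowed_z = mc$meanZ[i],
      size_mb = mc$sizeMb[i]
    )
    if ("arms" %in% colnames(mc)) {
      out$arms <- mc$arms[i]
      out$class <- mc$class[i]
    }
    out
  })
}

#' Write a cohort report to JSON
#'
#' @param report list from [screenReport()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
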