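## Bundled worked example: the per-subject screen results and arm-level
## CNV calls of a published 64-subject HGSOC plasma screening cohort
## (32 cases: 16 early, 16 advanced; 32 benign controls), encoded from the
## study's printed summary tables. Subjects S01-S13 are the screen-positive
## cancer cases and S14-S15 the two screen-positive controls; subject ids
## beyond S15 are placeholders for the screen-negative subjects, whose
## per-subject details were not printed.

#' Load the worked-example cohort manifest
#'
#' 64 subjects with group (`case`/`control`), stage label
#' (`early`/`advanced`/`control`), the >= 15 Mb screen result and the
#' routine NIPT pipeline call.
#'
#' @return a data.frame with one row per subject.
#' @seealso [loadWorkedExampleCalls()], [workedExampleReport()]
#' @export
loadWorkedExampleManifest <- function() {
  utils::read.delim(
    system.file("extdata", "hgsoc_worked_example_manifest.tsv",
                package = "cfScreen", mustWork = TRUE),
    sep = "\t", stringsAsFactors = FALSE
  )
}

#' Load the worked-example per-subject CNV calls
#'
#' One row per reported arm-level call of the screen-positive subjects:
#' `subject_id`, `group`, `stage_label`, `arm`, `direction`. Whole
#' chromosome entries are encoded with a bare chromosome token (e.g.
#' `"13"`); [expandWholeChromArms()] maps them to arms.
#'
#' @return a data.frame of calls.
#' @export
loadWorkedExampleCalls <- function() {
  utils::read.delim(
    system.file("extdata", "hgsoc_worked_example_calls.tsv",
                package = "cfScreen", mustWork = TRUE),
    sep = "\t", stringsAsFactors = FALSE,
    colClasses = c(arm = "character")
  )
}

## chromosomes whose p arm is a heterochromatic stalk: whole-chromosome
## events on these are arm events on q only
.ACROCENTRIC <- c("13", "14", "15", "21", "22")

#' Expand whole-chromosome call tokens to chromosome arms
#'
#' Bare chromosome tokens become one row per arm: both p and q for
#' metacentric chromosomes, q only for the acrocentric chromosomes
#' (13, 14, 15, 21, 22), whose p arms carry no unique sequence in this
#' binning. Rows that already name an arm pass through unchanged.
#'
#' @param calls data.frame with columns `arm` and `direction` (plus any
#'   others, carried along).
#' @return the expanded data.frame.
#' @export
expandWholeChromArms <- function(calls) {
  isWhole <- !grepl("[pq]$", calls$arm)
  if (!any(isWhole)) return(calls)
  whole <- calls[isWhole, , drop = FALSE]
  expand <- function(row) {
    arms <- if (row$arm %in% .ACROCENTRIC) paste0(row$arm, "q")
            else paste0(row$arm, c("p", "q"))
    out <- row[rep(1L, length(arms)), , drop = FALSE]
    out$arm <- arms
    out
  }
  expanded <- do.call(rbind, lapply(seq_len(nrow(whole)),
                                    function(i) expand(whole[i, , drop = FALSE])))
  out <- rbind(calls[!isWhole, , drop = FALSE], expanded)
  rownames(out) <- NULL
  out
}

#' Recompute the worked-example performance report
#'
#' Runs the full evaluation layer on the bundled cohort fixtures: confusion
#' counts and exact sensitivity/specificity intervals from the manifest,
#' arm expansion and catalog classification of the screen-positive calls,
#' per-arm tallies over true positives, and the count of true-positive
#' subjects with at least one highly specific CNV.
#'
#' @param catalog a [CNVCatalog-class] (default [defaultCatalog()]).
#' @return the list from [performanceReport()].
#' @examples
#' rep <- workedExampleReport()
#' rep$sensitivity$pct  # 40.6
#' @export
workedExampleReport <- function(catalog = defaultCatalog()) {
  manifest <- loadWorkedExampleManifest()
  calls <- data.frame(sample_id = manifest$subject_id,
                      status = manifest$screen_result,
                      stringsAsFactors = FALSE)
  counts <- confusionTable(
    calls,
    data.frame(sample_id = manifest$subject_id, group = manifest$group,
               stage_label = manifest$stage_label, stringsAsFactors = FALSE)
  )
  cnvs <- expandWholeChromArms(loadWorkedExampleCalls())
  tp <- cnvs[cnvs$group == "case", , drop = FALSE]
  tp$class <- classifyCNV(tp$arm, tp$direction, catalog)
  performanceReport(counts, annotations = tp)
}
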