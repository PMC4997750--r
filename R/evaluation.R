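## Cohort-level screening performance: confusion counts, exact binomial
## confidence intervals, per-arm event tallies.

#' Confusion counts for a screened cohort
#'
#' Matches per-subject screen calls against manifest labels: positives
#' among cases are true positives, positives among controls false
#' positives, and so on. Per-stage sub-counts are retained for the
#' case group.
#'
#' @param calls list of [ScreenCall-class] objects, or a data.frame with
#'   columns `sample_id` and `status` (`positive`/`negative`).
#' @param manifest data.frame with columns `sample_id`, `group`
#'   (`case`/`control`) and optionally `stage_label`.
#' @return list with `tp`, `fp`, `tn`, `fn` and `byStage` (a data.frame of
#'   detected / total per case stage).
#' @export
confusionTable <- function(calls, manifest) {
  if (is.list(calls) && !is.data.frame(calls)) {
    calls <- data.frame(
      sample_id = vapply(calls, sampleId, character(1)),
      status = vapply(calls, screenStatus, character(1)),
      stringsAsFactors = FALSE
    )
  }
  m <- match(calls$sample_id, manifest$sample_id)
  if (anyNA(m))
    stop("sample id not in manifest: ",
         paste(calls$sample_id[is.na(m)], collapse = ", "))
  group <- manifest$group[m]
  pos <- calls$status == "positive"
  isCase <- group == "case"
  byStage <- if ("stage_label" %in% colnames(manifest) && any(isCase)) {
    st <- manifest$stage_label[m][isCase]
    agg <- stats::aggregate(pos[isCase], by = list(stage = st),
                            FUN = function(x) c(sum(x), length(x)))
    data.frame(stage = agg$stage, detected = agg$x[, 1], total = agg$x[, 2],
               stringsAsFactors = FALSE)
  } else {
    data.frame(stage = character(), detected = integer(), total = integer())
  }
  list(
    tp = sum(pos & isCase), fn = sum(!pos & isCase),
    fp = sum(pos & !isCase), tn = sum(!pos & !isCase),
    byStage = byStage
  )
}

#' Exact (Clopper-Pearson) binomial confidence interval, in percent
#'
#' Two-sided exact interval from beta quantiles:
#' lower `= qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`), upper
#' `= qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`). Returned in
#' percent at full precision; reports round to one decimal.
#'
#' @param successes number of successes (`0 <= successes <= trials`).
#' @param trials number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower, upper)` in percent.
#' @examples
#' round(binomialCiExact(13, 32), 1) # 23.7 59.4
#' @export
binomialCiExact <- function(successes, trials, level = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials ||
      successes != round(successes) || trials != round(trials))
    stop("need integer counts with 0 <= successes <= trials, trials >= 1")
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(lower = lower * 100, upper = upper * 100)
}

#' Round half-up to a number of decimals
#'
#' Display rounding for report percentages (base `round()` rounds half to
#' even, which would print 93.75 % inconsistently with clinical reports).
#'
#' @param x numeric.
#' @param digits decimals (default 1).
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Cohort screening performance report
#'
#' Sensitivity `= TP / (TP + FN)` and specificity `= TN / (TN + FP)` in
#' percent (half-up to one decimal) with exact 95 % confidence intervals,
#' per-stage detection, and — when per-subject annotations are supplied —
#' per-arm event tallies over true positives and the number of true
#' positives carrying at least one highly specific CNV. A zero denominator
#' yields an `NA` estimate with no interval.
#'
#' @param counts list from [confusionTable()].
#' @param annotations optional data.frame of true-positive subjects'
#'   annotated calls with columns `subject_id`, `arm`, `direction`,
#'   `class`.
#' @param level confidence level (default 0.95).
#' @return list with `sensitivity`, `specificity` (each: `pct`, `ci`,
#'   `successes`, `trials`), `byStage`, and optionally `armTally` and
#'   `highlySpecificSubjects`.
#' @export
performanceReport <- function(counts, annotations = NULL, level = 0.95) {
  est <- function(x, n) {
    if (n == 0) return(list(pct = NA_real_, ci = NULL, successes = x, trials = n))
    list(pct = roundHalfUp(100 * x / n, 1),
         ci = roundHalfUp(binomialCiExact(x, n, level), 1),
         successes = x, trials = n)
  }
  out <- list(
    sensitivity = est(counts$tp, counts$tp + counts$fn),
    specificity = est(counts$tn, counts$tn + counts$fp),
    counts = counts[c("tp", "fn", "fp", "tn")],
    byStage = counts$byStage
  )
  if (!is.null(annotations) && nrow(annotations)) {
    out$armTally <- armEventTally(annotations)
    hs <- tapply(annotations$class == "highly_specific",
                 annotations$subject_id, any)
    out$highlySpecificSubjects <- sum(hs)
    out$annotatedSubjects <- length(hs)
  }
  out
}

#' Per-(arm, direction) subject tallies
#'
#' For each `(arm, direction)` pair, the number of distinct subjects with
#' at least one such call — a subject counts once per pair however many
#' segments hit the arm.
#'
#' @param annotations data.frame with columns `subject_id`, `arm`,
#'   `direction`.
#' @return data.frame `arm`, `direction`, `n`, sorted by decreasing `n`.
#' @export
armEventTally <- function(annotations) {
  if (!nrow(annotations))
    return(data.frame(arm = character(), direction = character(),
                      n = integer(), stringsAsFactors = FALSE))
  u <- unique(annotations[, c("subject_id", "arm", "direction")])
  agg <- stats::aggregate(u$subject_id,
                          by = list(arm = u$arm, direction = u$direction),
                          FUN = length)
  names(agg)[3] <- "n"
  agg[order(-agg$n, agg$arm), ]
}
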