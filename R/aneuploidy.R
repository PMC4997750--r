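## Simplified NIPT-style whole-chromosome aneuploidy screen.
##
## The routine prenatal pipeline scores each target chromosome's read
## fraction against a reference panel (the normalized chromosome value,
## NCV) and refuses to report when non-target "normalizing" chromosomes
## deviate — the behavior cancer-like multi-aberration profiles trigger.
## This module reproduces that method class with a generic z statistic; it
## makes no attempt to reproduce any proprietary pipeline numerically, and
## reports flag the QC rule as an approximation.

#' Per-chromosome read fractions of a sample
#'
#' Sums normalized usable-bin values per chromosome. Because normalization
#' is against the usable autosomal total, autosomal fractions sum to 1 and
#' the X fraction is on the same scale.
#'
#' @param profile a normalized (and usually GC-corrected)
#'   [SampleProfile-class].
#' @return named numeric vector of fractions, one per chromosome.
#' @export
chromosomeFractions <- function(profile) {
  stopifnot(is(profile, "SampleProfile"))
  if (!profile@normalized) stop("normalize the profile first")
  grid <- profile@grid
  use <- usableBins(grid)
  ch <- factor(.gridChrom(grid)[use], levels = unique(.gridChrom(grid)))
  f <- tapply(profile@values[use], ch, sum)
  stats::setNames(as.numeric(f), levels(ch))
}

## Chromosome fractions are compositional: a large aberration on one
## chromosome shifts every other fraction through the shared autosomal
## total. Before z-scoring, each sample is therefore rescaled by the median
## of its per-autosome fraction/reference-mean ratios (a median-of-ratios
## size factor, robust to several genuinely aberrant chromosomes), so an
## aneuploid chromosome cannot drag the normalizing chromosomes with it.
.mofScale <- function(fractions, refMean) {
  auto <- setdiff(names(refMean), "X")
  stats::median(fractions[auto] / refMean[auto])
}

#' Panel chromosome-fraction statistics
#'
#' Mean and standard deviation (n-1 denominator) of per-chromosome read
#' fractions across a reference panel, the baseline for NCV z-scores.
#' Fractions are stabilized by a median-of-ratios rescaling (each sample
#' divided by the median, over autosomes, of its fraction relative to the
#' panel mean) so that the statistics match how case samples are scored.
#'
#' @param panel list of normalized, GC-corrected [SampleProfile-class]
#'   objects (>= 10 recommended for a stable sd).
#' @return list with named vectors `mean` and `sd`.
#' @export
panelChromStats <- function(panel) {
  if (length(panel) < 2) stop("panel must contain at least 2 samples")
  if (length(panel) < 10)
    warning("fewer than 10 panel samples; chromosome sd estimates are unstable")
  F <- do.call(rbind, lapply(panel, chromosomeFractions))
  m0 <- colMeans(F)
  Fs <- t(apply(F, 1, function(f) f / .mofScale(f, m0)))
  colnames(Fs) <- colnames(F)
  list(mean = colMeans(Fs), sd = apply(Fs, 2, stats::sd))
}

#' Normalized chromosome value (NCV) z-scores
#'
#' `z_c = (fraction_c / s - panel mean_c) / panel sd_c` for every
#' chromosome in the panel statistics, where `s` is the sample's
#' median-of-ratios scale factor over autosomes. For a euploid sample
#' `s` is 1 up to noise; for an aneuploid sample it absorbs the
#' compositional shift the aberration forces on all other chromosomes, so
#' only genuinely deviant chromosomes score high.
#'
#' @param fractions named fractions from [chromosomeFractions()].
#' @param panelStats list from [panelChromStats()].
#' @return named numeric z-scores.
#' @export
ncvScores <- function(fractions, panelStats) {
  chroms <- names(panelStats$mean)
  if (any(panelStats$sd[chroms] == 0))
    stop("panel chromosome sd is zero for: ",
         paste(chroms[panelStats$sd[chroms] == 0], collapse = ", "))
  s <- .mofScale(fractions[chroms], panelStats$mean)
  (fractions[chroms] / s - panelStats$mean[chroms]) / panelStats$sd[chroms]
}

#' Classify a sample's aneuploidy screen result
#'
#' QC first: if any non-target autosome has `|z| > qcThreshold` the sample
#' is a `no_call` (normalizing-chromosome failure) and no risk calls are
#' issued. Otherwise each target chromosome is called `high_risk_gain`
#' (`z >= callThreshold`), `high_risk_loss` (`z <= -callThreshold`) or
#' `low_risk`; losses are labeled "monosomy 18", "monosomy X", etc.
#'
#' @param z named per-chromosome z-scores from [ncvScores()].
#' @param targets target chromosomes (default `c("13", "18", "21", "X")`;
#'   chromosome Y is out of scope for an all-female screening population).
#' @param callThreshold `|z|` for a high-risk call (default 4).
#' @param qcThreshold `|z|` on non-target autosomes that triggers a no-call
#'   (default 3).
#' @param sampleId sample identifier carried into the result.
#' @param fractions optional named fractions stored in the result.
#' @return an [AneuploidyResult-class].
#' @export
classifyAneuploidy <- function(z, targets = c("13", "18", "21", "X"),
                               callThreshold = 4, qcThreshold = 3,
                               sampleId = "sample", fractions = numeric()) {
  qcChroms <- setdiff(names(z), c(targets, "X"))
  bad <- qcChroms[abs(z[qcChroms]) > qcThreshold]
  if (length(bad)) {
    worst <- bad[which.max(abs(z[bad]))]
    return(new("AneuploidyResult",
      sampleId = sampleId, status = "no_call",
      reason = sprintf(
        "unexpected profile on normalizing chromosome %s (z = %.1f)",
        worst, z[[worst]]
      ),
      fractions = fractions, z = z,
      calls = character(), labels = character()
    ))
  }
  calls <- vapply(targets, function(ch) {
    if (z[[ch]] >= callThreshold) "high_risk_gain"
    else if (z[[ch]] <= -callThreshold) "high_risk_loss"
    else "low_risk"
  }, character(1))
  labels <- vapply(targets, function(ch) {
    if (z[[ch]] >= callThreshold) paste("trisomy", ch)
    else if (z[[ch]] <= -callThreshold) paste("monosomy", ch)
    else ""
  }, character(1))
  new("AneuploidyResult",
    sampleId = sampleId, status = "reported", reason = "",
    fractions = fractions, z = z,
    calls = stats::setNames(calls, targets),
    labels = stats::setNames(labels, targets)
  )
}

#' Run the aneuploidy screen on one sample
#'
#' Convenience wrapper: fractions, NCV z-scores and classification in one
#' call.
#'
#' @param profile a [SampleProfile-class] (normalized on the fly if raw).
#' @param panelStats list from [panelChromStats()].
#' @param ... passed to [classifyAneuploidy()].
#' @return an [AneuploidyResult-class].
#' @export
aneuploidyScreen <- function(profile, panelStats, ...) {
  if (!profile@normalized) profile <- normalizeCounts(profile)
  if (!profile@gcCorrected) profile <- gcCorrect(profile)
  f <- chromosomeFractions(profile)
  z <- ncvScores(f, panelStats)
  classifyAneuploidy(z, sampleId = profile@sampleId, fractions = f, ...)
}
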