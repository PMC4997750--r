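## Within-sample-reference CNV caller.
##
## Pipeline: normalizeCounts -> gcCorrect -> (panel) buildReferenceIndex ->
## scoreBins -> windowedScores -> callSegments. Each usable bin is scored
## against the k other-chromosome bins that behave most like it across a
## copy-neutral reference panel, so sample-wide biases cancel within the
## sample itself; per-bin z-scores are combined over sliding windows by
## Stouffer's method and same-sign super-threshold runs become segments.

#' Normalize raw bin counts to fractions of the autosomal total
#'
#' Each usable bin's value becomes its count divided by the total count over
#' usable autosomal bins. X-chromosome bins are divided by the same
#' autosomal total, so X dosage is scorable without perturbing autosomal
#' values. Unusable bins stay `NA`.
#'
#' @param profile a raw-count [SampleProfile-class].
#' @return the profile with normalized values set.
#' @export
normalizeCounts <- function(profile) {
  stopifnot(is(profile, "SampleProfile"))
  grid <- profile@grid
  ua <- autosomalUsable(grid)
  total <- sum(profile@counts[ua])
  if (total <= 0) stop("total usable autosomal count is zero")
  values <- rep(NA_real_, nBins(grid))
  use <- usableBins(grid)
  values[use] <- profile@counts[use] / total
  methods::initialize(profile, values = values, normalized = TRUE)
}

#' Correct normalized values for GC bias
#'
#' Fits a locally-weighted regression (loess, span 0.3) of normalized value
#' against bin GC over usable autosomal bins, divides every usable bin's
#' value by the fit at its GC (clamped to the fitted GC range), and
#' renormalizes so usable autosomal values again sum to 1. With fewer than
#' 50 usable autosomal bins the correction is skipped with a warning; a
#' profile that is already GC-corrected is returned unchanged (the
#' correction is applied at most once).
#'
#' @param profile a normalized [SampleProfile-class].
#' @param span loess span (default 0.3).
#' @return the corrected profile (`gcCorrected = TRUE`).
#' @export
gcCorrect <- function(profile, span = 0.3) {
  stopifnot(is(profile, "SampleProfile"))
  if (!profile@normalized) stop("normalize counts before GC correction")
  if (profile@gcCorrected) return(profile)
  grid <- profile@grid
  ua <- autosomalUsable(grid)
  if (sum(ua) < 50) {
    warning("fewer than 50 usable autosomal bins; GC correction skipped")
    return(profile)
  }
  gc <- .gridGC(grid)
  v <- profile@values
  rng <- range(gc[ua])
  if (diff(rng) < 1e-8) {
    # no GC spread: the fit is a constant and correction is the identity
    return(methods::initialize(profile, gcCorrected = TRUE))
  }
  fit <- stats::loess(v[ua] ~ gc[ua], span = span, degree = 2,
                      family = "gaussian")
  use <- usableBins(grid)
  pred <- stats::predict(fit, newdata = pmin(pmax(gc[use], rng[1]), rng[2]))
  if (any(!is.finite(pred) | pred <= 0))
    stop("GC fit produced non-positive or missing predictions")
  values <- rep(NA_real_, length(v))
  values[use] <- v[use] / pred
  values[use] <- values[use] / sum(values[ua])
  methods::initialize(profile, values = values, gcCorrected = TRUE)
}

## grids must agree in coordinates for cross-object operations
.sameGrid <- function(a, b) {
  length(a@bins) == length(b@bins) &&
    identical(.gridChrom(a), .gridChrom(b)) &&
    identical(.gridStart0(a), .gridStart0(b)) &&
    identical(.gridEnd0(a), .gridEnd0(b))
}

## panel profiles as a samples x usable-bins value matrix
.panelMatrix <- function(panel, grid) {
  use <- which(usableBins(grid))
  V <- do.call(rbind, lapply(panel, function(p) {
    if (!.sameGrid(p@grid, grid)) stop("panel profiles are on different grids")
    if (!p@normalized) stop("panel profiles must be normalized (and GC-corrected)")
    p@values[use]
  }))
  list(V = V, use = use)
}

#' Build the within-sample reference index from a panel
#'
#' For each usable bin `i`, ranks all other eligible usable bins `j` by the
#' squared distance `d(i, j) = sum over panel samples of (v_si - v_sj)^2`
#' of their normalized, GC-corrected values, and keeps the `k` nearest
#' (ties broken by grid order). Eligible bins exclude bin `i` itself, by
#' default every bin on the same chromosome (so whole-chromosome events are
#' not self-normalized away), and X-chromosome bins (female X dosage must
#' not leak into autosomal references). The index also stores the panel
#' mean `mu_i` and sample standard deviation `sigma_i` (n-1 denominator,
#' floored at `1e-4 * mu_i`) of the reference ratio
#' `r_si = v_si / mean(v_s over ref(i))`.
#'
#' `mu_i` and `sigma_i` are estimated leave-one-out: for each panel sample
#' the reference bins are re-selected from distances excluding that
#' sample's own contribution, so `sigma_i` measures out-of-sample ratio
#' variability. Selecting references and measuring their spread on the
#' same samples would understate `sigma_i` (the selection partially fits
#' the panel's noise) and inflate every downstream z-score by 15-20 %.
#'
#' @param panel list of normalized, GC-corrected [SampleProfile-class]
#'   objects on a common grid (>= 2).
#' @param k reference bins per bin (default 100).
#' @param excludeSameChrom exclude same-chromosome bins from references
#'   (default `TRUE`).
#' @param sigmaFloorFrac floor for `sigma_i` as a fraction of `mu_i`
#'   (default 1e-4).
#' @return a [ReferenceIndex-class].
#' @export
buildReferenceIndex <- function(panel, k = 100, excludeSameChrom = TRUE,
                                sigmaFloorFrac = 1e-4) {
  if (length(panel) < 2) stop("reference panel must contain at least 2 samples")
  if (k < 1) stop("k must be at least 1")
  grid <- panel[[1]]@grid
  pm <- .panelMatrix(panel, grid)
  V <- pm$V
  use <- pm$use
  nb <- length(use)
  chrom <- .gridChrom(grid)[use]
  eligible <- chrom != "X"

  ## all pairwise squared distances via the crossprod identity
  ss <- colSums(V^2)
  D <- outer(ss, ss, "+") - 2 * crossprod(V)
  D[D < 0] <- 0  # numerical noise

  refIdx <- matrix(0L, nrow = k, ncol = nb)
  for (i in seq_len(nb)) {
    d <- D[, i]
    d[i] <- Inf
    d[!eligible] <- Inf
    if (excludeSameChrom) d[chrom == chrom[i]] <- Inf
    ok <- is.finite(d)
    if (sum(ok) < k)
      stop(sprintf("bin %s:%d has only %d eligible reference bins (k = %d)",
                   chrom[i], .gridStart0(grid)[use[i]], sum(ok), k))
    refIdx[, i] <- order(d, seq_along(d))[seq_len(k)]
  }

  ## leave-one-out panel ratio statistics: each held-out sample's ratio
  ## uses reference bins re-selected on the remaining samples, so sigma
  ## measures out-of-sample ratio variability (selecting and scoring on
  ## the same samples understates sigma and inflates downstream z-scores)
  chromId <- as.integer(factor(chrom, levels = unique(chrom)))
  R <- .looRatioMatrix(D, V, chromId, eligible, as.integer(k),
                       excludeSameChrom)
  mu <- colMeans(R)
  sigma <- sqrt(colSums((R - rep(mu, each = nrow(R)))^2) / (nrow(R) - 1))
  sigma <- pmax(sigma, sigmaFloorFrac * mu)

  new("ReferenceIndex",
    grid = grid, usableIdx = as.integer(use), refIdx = refIdx,
    mu = mu, sigma = sigma, k = as.integer(k),
    panelSize = length(panel), excludeSameChrom = excludeSameChrom
  )
}

#' Score a sample's bins against the reference index
#'
#' Computes each usable bin's reference ratio
#' `r_i = v_i / mean(v over ref(i))` from the sample's normalized,
#' GC-corrected values and standardizes it against the panel:
#' `z_i = (r_i - mu_i) / sigma_i`.
#'
#' @param profile a normalized, GC-corrected [SampleProfile-class] (not a
#'   panel member).
#' @param index a [ReferenceIndex-class] on the same grid.
#' @return a [ZProfile-class] with the individual z track (windowed track
#'   unset).
#' @export
scoreBins <- function(profile, index) {
  stopifnot(is(profile, "SampleProfile"), is(index, "ReferenceIndex"))
  if (!.sameGrid(profile@grid, index@grid))
    stop("sample grid does not match the reference index grid")
  if (!profile@normalized) stop("normalize (and GC-correct) the sample first")
  v <- profile@values[index@usableIdx]
  denom <- colMeans(matrix(v[index@refIdx], nrow = nrow(index@refIdx)))
  r <- v / denom
  z <- (r - index@mu) / index@sigma
  new("ZProfile",
    sampleId = profile@sampleId, grid = index@grid,
    usableIdx = index@usableIdx, z = z,
    zWindowed = rep(NA_real_, length(z)), window = NA_integer_
  )
}

#' Combine individual z-scores over sliding windows (Stouffer's method)
#'
#' For each scored bin, sums the individual z-scores over the `w`-bin
#' window centered on it — truncated at chromosome ends, never spanning
#' chromosomes — and divides by the square root of the actual window size.
#'
#' @param zprofile a [ZProfile-class] with the individual track.
#' @param w window width in bins (odd, >= 1; default 7).
#' @return the profile with the windowed track filled in.
#' @export
windowedScores <- function(zprofile, w = 7) {
  stopifnot(is(zprofile, "ZProfile"))
  if (w < 1 || w %% 2 == 0) stop("window width must be an odd positive count")
  half <- (w - 1) / 2
  chrom <- .gridChrom(zprofile@grid)[zprofile@usableIdx]
  Z <- numeric(length(zprofile@z))
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    z <- zprofile@z[ix]
    n <- length(z)
    cs <- c(0, cumsum(z))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    Z[ix] <- (cs[hi + 1L] - cs[lo]) / sqrt(hi - lo + 1L)
  }
  methods::initialize(zprofile, zWindowed = Z, window = as.integer(w))
}

#' Call copy-number segments from the windowed z track
#'
#' Bins with `|Z| >= callThreshold` are marked. Runs of same-sign marked
#' bins on one chromosome — allowing up to `mergeGap` unmarked bins between
#' consecutive marked bins — are merged into segments spanning from the
#' first to the last marked bin. Direction follows the sign; the mean
#' windowed Z over the marked bins is reported. Segment boundaries are the
#' marked-bin span; no sub-bin refinement is attempted, so at a 15 Mb
#' decision scale boundaries are exact multiples of the bin size.
#'
#' @param zprofile a windowed [ZProfile-class].
#' @param callThreshold `|Z|` threshold for marking bins (default 3.5).
#' @param mergeGap maximum unmarked bins bridged within a run (default 2).
#' @return a `GRanges` of segments with metadata columns `direction`
#'   (`gain`/`loss`), `meanZ`, `nBins` (marked bins) and `sizeMb`
#'   (`(end - start) / 1e6` in 0-based half-open bp).
#' @export
callSegments <- function(zprofile, callThreshold = 3.5, mergeGap = 2) {
  stopifnot(is(zprofile, "ZProfile"))
  if (is.na(zprofile@window)) stop("windowed track missing; run windowedScores()")
  idx <- zprofile@usableIdx
  chrom <- .gridChrom(zprofile@grid)[idx]
  st0 <- .gridStart0(zprofile@grid)[idx]
  en0 <- .gridEnd0(zprofile@grid)[idx]
  Z <- zprofile@zWindowed

  segs <- list()
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    marked <- ix[abs(Z[ix]) >= callThreshold]
    if (!length(marked)) next
    sgn <- sign(Z[marked])
    ## position within the chromosome's usable-bin axis
    pos <- match(marked, ix)
    runStart <- 1L
    flush <- function(a, b) {
      mb <- marked[a:b]
      segs[[length(segs) + 1L]] <<- data.frame(
        chrom = ch, start = st0[mb[1L]], end = en0[mb[length(mb)]],
        direction = if (sgn[a] > 0) "gain" else "loss",
        meanZ = mean(Z[mb]), nBins = length(mb),
        stringsAsFactors = FALSE
      )
    }
    for (j in seq_along(marked)[-1]) {
      gap <- pos[j] - pos[j - 1L] - 1L
      if (sgn[j] != sgn[j - 1L] || gap > mergeGap) {
        flush(runStart, j - 1L)
        runStart <- j
      }
    }
    flush(runStart, length(marked))
  }
  if (!length(segs)) return(.emptySegments())
  tab <- do.call(rbind, segs)
  gr <- GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$start + 1, tab$end))
  S4Vectors::mcols(gr)$direction <- tab$direction
  S4Vectors::mcols(gr)$meanZ <- tab$meanZ
  S4Vectors::mcols(gr)$nBins <- tab$nBins
  S4Vectors::mcols(gr)$sizeMb <- (tab$end - tab$start) / 1e6
  gr
}

.emptySegments <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr)$direction <- character()
  S4Vectors::mcols(gr)$meanZ <- numeric()
  S4Vectors::mcols(gr)$nBins <- integer()
  S4Vectors::mcols(gr)$sizeMb <- numeric()
  gr
}

#' Run the full caller on one sample
#'
#' Convenience wrapper: [normalizeCounts()] and [gcCorrect()] (if not
#' already applied), then [scoreBins()], [windowedScores()] and
#' [callSegments()].
#'
#' @param profile a [SampleProfile-class] (raw or normalized).
#' @param index a [ReferenceIndex-class].
#' @param w window width (default 7).
#' @param callThreshold windowed-z call threshold (default 3.5).
#' @param mergeGap run merge gap in bins (default 2).
#' @return list with elements `zprofile` (windowed [ZProfile-class]) and
#'   `segments` (`GRanges`).
#' @export
callSample <- function(profile, index, w = 7, callThreshold = 3.5,
                       mergeGap = 2) {
  if (!profile@normalized) profile <- normalizeCounts(profile)
  if (!profile@gcCorrected) profile <- gcCorrect(profile)
  zp <- windowedScores(scoreBins(profile, index), w = w)
  list(zprofile = zp,
       segments = callSegments(zp, callThreshold = callThreshold,
                               mergeGap = mergeGap))
}

#' Prepare a raw panel for index building
#'
#' Normalizes and GC-corrects every profile in a list.
#'
#' @param panel list of [SampleProfile-class] objects.
#' @return list of normalized, GC-corrected profiles.
#' @export
preparePanel <- function(panel) {
  lapply(panel, function(p) {
    if (!p@normalized) p <- normalizeCounts(p)
    if (!p@gcCorrected) p <- gcCorrect(p)
    p
  })
}
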