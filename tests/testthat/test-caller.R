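# Within-sample-reference caller: normalization, GC correction, reference
# index, z-scores, windows, segmentation.

test_that("normalization divides by the usable autosomal total", {
  grid <- miniGrid(1, 3)
  prof <- normalizeCounts(SampleProfile("s", grid, c(2, 1, 1)))
  expect_equal(normValues(prof), c(0.5, 0.25, 0.25))
  expect_error(normalizeCounts(SampleProfile("z", grid, c(0, 0, 0))), "zero")

  # X bins are scored on the autosomal scale, not part of the total
  gx <- BinGrid(c("1", "1", "X"), c(0, 1e6, 0), c(1e6, 2e6, 1e6),
                gc = c(0.4, 0.4, 0.4))
  px <- normalizeCounts(SampleProfile("s", gx, c(3, 1, 2)))
  expect_equal(normValues(px), c(0.75, 0.25, 0.5))

  # simulated samples satisfy the sum invariant exactly
  sim <- normalizeCounts(simulateSample(toyGrid(), seed = 2))
  ua <- cfScreen:::autosomalUsable(toyGrid())
  expect_equal(sum(normValues(sim)[ua]), 1, tolerance = 1e-12)
})

test_that("GC correction flattens a linear GC bias and applies only once", {
  grid <- toyGrid()
  gc <- cfScreen:::.gridGC(grid)
  ua <- cfScreen:::autosomalUsable(grid)
  for (s in c(21, 22, 23)) {
    prof <- normalizeCounts(simulateSample(grid, simParams(gcSlopeSd = 0.5),
                                           seed = s))
    corrected <- gcCorrect(prof)
    expect_lt(abs(cor(normValues(corrected)[ua], gc[ua])), 0.05)
    expect_equal(sum(normValues(corrected)[ua]), 1, tolerance = 1e-9)
    # applying the correction twice changes nothing
    twice <- gcCorrect(corrected)
    expect_identical(normValues(twice), normValues(corrected))
  }

  # constant-GC grid: the fit is a constant, values unchanged
  gflat <- miniGrid(1, 60, gc = rep(0.42, 60))
  pf <- normalizeCounts(SampleProfile("f", gflat, rpois(60, 1000)))
  cf <- gcCorrect(pf)
  expect_equal(normValues(cf), normValues(pf), tolerance = 1e-9)

  # too few bins: correction skipped with a warning
  small <- miniGrid(1, 10)
  ps <- normalizeCounts(SampleProfile("s", small, rep(100, 10)))
  expect_warning(out <- gcCorrect(ps), "skipped")
  expect_identical(normValues(out), normValues(ps))
})

test_that("reference-bin selection matches an exhaustive brute-force search", {
  grid <- miniGrid(3, 15)
  set.seed(31)
  panel <- lapply(1:5, function(s) {
    valueProfile(grid, abs(rnorm(45, 100, 10)), sprintf("p%d", s))
  })
  idx <- buildReferenceIndex(panel, k = 3)
  V <- do.call(rbind, lapply(panel, normValues))
  chrom <- cfScreen:::.gridChrom(grid)
  oracle <- bruteRefIndex(V, chrom, k = 3)
  expect_identical(idx@refIdx, oracle$refIdx)
  expect_equal(idx@mu, oracle$mu, tolerance = 1e-12)
  expect_equal(idx@sigma, oracle$sigma, tolerance = 1e-12)

  # same-chromosome inclusion when the exclusion is turned off
  idx2 <- buildReferenceIndex(panel, k = 3, excludeSameChrom = FALSE)
  oracle2 <- bruteRefIndex(V, chrom, k = 3, excludeSameChrom = FALSE)
  expect_identical(idx2@refIdx, oracle2$refIdx)
})

test_that("distance ties resolve to the lowest (chromosome, start) bins", {
  grid <- miniGrid(3, 5)
  panel <- lapply(1:3, function(s) valueProfile(grid, rep(1, 15), paste0("p", s)))
  idx <- buildReferenceIndex(panel, k = 4)
  # for a chromosome-1 bin all distances tie at 0: references must be the
  # first eligible bins in grid order, i.e. the start of chromosome 2
  expect_identical(idx@refIdx[, 1], 6:9)
  # for a chromosome-2 bin: chromosome 1 opens the eligible set
  expect_identical(idx@refIdx[, 6], 1:4)
})

test_that("k larger than the eligible bin count is rejected by name", {
  grid <- miniGrid(2, 5)
  panel <- lapply(1:3, function(s) valueProfile(grid, rep(1, 10), paste0("p", s)))
  expect_error(buildReferenceIndex(panel, k = 6), "eligible reference bins")
})

test_that("panel ratio means sit near 1 for a copy-neutral panel", {
  fx <- fullFixtures()
  dev <- abs(fx$index@mu - 1)
  expect_lt(median(dev), 0.01)
  expect_gt(mean(dev <= 0.05), 0.98)
  expect_true(all(fx$index@sigma > 0))
})

test_that("z-scores respond to the sample, not the panel, with correct sign", {
  grid <- miniGrid(3, 15)
  set.seed(77)
  panel <- lapply(1:20, function(s) {
    valueProfile(grid, abs(rnorm(45, 100, 5)), sprintf("p%d", s))
  })
  idx <- buildReferenceIndex(panel, k = 5)

  # a sample sitting at the panel per-bin means scores near zero everywhere
  V <- do.call(rbind, lapply(panel, normValues))
  atMean <- valueProfile(grid, colMeans(V), "mean")
  zp <- scoreBins(atMean, idx)
  expect_true(all(abs(individualZ(zp)) < 0.5))

  # inflating one bin while its references stay put raises its z
  v <- colMeans(V)
  v[20] <- v[20] * 2
  zUp <- individualZ(scoreBins(valueProfile(grid, v, "up"), idx))
  expect_gt(zUp[20], 1)

  # grid mismatch is refused
  other <- valueProfile(miniGrid(3, 14), rep(1, 42), "other")
  expect_error(scoreBins(other, idx), "grid")
})

test_that("null samples produce calibrated per-bin z-scores", {
  fx <- fullFixtures()
  sds <- vapply(1:3, function(i) {
    s <- gcCorrect(normalizeCounts(simulateSample(fx$grid, seed = 400 + i)))
    sd(individualZ(scoreBins(s, fx$index)))
  }, numeric(1))
  expect_true(all(sds > 0.8 & sds < 1.2))
})

test_that("windowed scores follow the Stouffer closed forms", {
  grid <- miniGrid(1, 7)
  mk <- function(z) {
    methods::new("ZProfile", sampleId = "t", grid = grid,
                 usableIdx = 1:7, z = z, zWindowed = rep(NA_real_, 7),
                 window = NA_integer_)
  }
  allOnes <- windowedScores(mk(rep(1, 7)), w = 7)
  expect_equal(windowedZ(allOnes)[4], sqrt(7))
  # truncated end windows: first bin sees bins 1..4
  expect_equal(windowedZ(allOnes)[1], 4 / sqrt(4))

  spike <- windowedScores(mk(c(0, 0, 0, 3, 0, 0, 0)), w = 7)
  expect_equal(windowedZ(spike)[4], 3 / sqrt(7))
  expect_equal(windowedZ(spike)[1], 3 / sqrt(4))

  zeros <- windowedScores(mk(rep(0, 7)), w = 7)
  expect_true(all(windowedZ(zeros) == 0))

  expect_error(windowedScores(mk(rep(1, 7)), w = 4), "odd")
})

test_that("windows never leak across chromosomes and match direct sums", {
  grid <- miniGrid(2, 10)
  z <- c(rep(2, 10), rep(0, 10))
  zp <- methods::new("ZProfile", sampleId = "t", grid = grid,
                     usableIdx = 1:20, z = z,
                     zWindowed = rep(NA_real_, 20), window = NA_integer_)
  Z <- windowedZ(windowedScores(zp, w = 7))
  expect_true(all(Z[11:20] == 0))          # chromosome 2 untouched
  expect_equal(Z[10], 4 * 2 / sqrt(4))     # truncated at the chromosome end

  set.seed(5)
  zr <- rnorm(20)
  zp2 <- methods::new("ZProfile", sampleId = "t", grid = grid,
                      usableIdx = 1:20, z = zr,
                      zWindowed = rep(NA_real_, 20), window = NA_integer_)
  chrom <- cfScreen:::.gridChrom(grid)
  for (w in c(1, 3, 7)) {
    expect_equal(windowedZ(windowedScores(zp2, w = w)),
                 bruteWindow(zr, chrom, w), tolerance = 1e-12)
  }
})

test_that("segmentation merges same-sign runs and matches the brute force", {
  grid <- miniGrid(1, 30)
  Z <- rep(0, 30); Z[6:25] <- 5
  segs <- callSegments(windowedZProfile(grid, Z))
  expect_length(segs, 1L)
  expect_equal(S4Vectors::mcols(segs)$direction, "gain")
  expect_equal(S4Vectors::mcols(segs)$sizeMb, 20.0)
  expect_equal(S4Vectors::mcols(segs)$nBins, 20L)
  expect_equal(GenomicRanges::start(segs) - 1, 5e6)
  expect_equal(GenomicRanges::end(segs), 25e6)

  # adjacent opposite-sign runs stay separate
  Z2 <- rep(0, 30); Z2[5:10] <- 5; Z2[11:16] <- -5
  segs2 <- callSegments(windowedZProfile(grid, Z2))
  expect_length(segs2, 2L)
  expect_setequal(S4Vectors::mcols(segs2)$direction, c("gain", "loss"))

  # sub-threshold tracks yield nothing
  expect_length(callSegments(windowedZProfile(grid, rep(3, 30))), 0L)

  # gaps up to mergeGap unmarked bins are bridged, longer gaps split
  Z3 <- rep(0, 30); Z3[5:8] <- 5; Z3[11:14] <- 5   # gap of 2
  expect_length(callSegments(windowedZProfile(grid, Z3), mergeGap = 2), 1L)
  Z4 <- rep(0, 30); Z4[5:8] <- 5; Z4[12:15] <- 5   # gap of 3
  expect_length(callSegments(windowedZProfile(grid, Z4), mergeGap = 2), 2L)

  # randomized equivalence against the independent implementation
  grid2 <- miniGrid(3, 15)
  chrom <- cfScreen:::.gridChrom(grid2)
  st0 <- cfScreen:::.gridStart0(grid2)
  en0 <- cfScreen:::.gridEnd0(grid2)
  set.seed(99)
  for (rep in 1:25) {
    Zr <- rnorm(45, sd = 3)
    got <- callSegments(windowedZProfile(grid2, Zr),
                        callThreshold = 3.5, mergeGap = 2)
    want <- bruteSegments(chrom, st0, en0, Zr, thr = 3.5, gap = 2)
    if (is.null(want)) {
      expect_length(got, 0L)
    } else {
      expect_equal(length(got), nrow(want))
      expect_equal(GenomicRanges::start(got) - 1, want$start)
      expect_equal(GenomicRanges::end(got), want$end)
      expect_equal(S4Vectors::mcols(got)$direction, want$direction)
      expect_equal(S4Vectors::mcols(got)$meanZ, want$meanZ, tolerance = 1e-12)
      expect_equal(S4Vectors::mcols(got)$nBins, as.integer(want$nBins))
    }
  }
})
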