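# Shared fixtures, built in code at test time.

# small 3-chromosome genome: exact 1 Mb multiples so every bin is usable
toyGenome <- function() {
  GenomeSpec(c("1", "2", "3"), c(60e6, 50e6, 40e6), c(25e6, 20e6, 18e6))
}

toyGrid <- function(binSize = 1e6) makeDefaultGrid(toyGenome(), binSize)

# tiny grid for hand-checkable examples: nChrom chromosomes x nBins 1 Mb bins
miniGrid <- function(nChrom = 3, nBinsPer = 15, gc = NULL) {
  chrom <- rep(as.character(seq_len(nChrom)), each = nBinsPer)
  start <- rep((seq_len(nBinsPer) - 1) * 1e6, nChrom)
  if (is.null(gc)) gc <- rep(seq(0.35, 0.5, length.out = nBinsPer), nChrom)
  BinGrid(chrom, start, start + 1e6, gc)
}

# profile with injected normalized values (bypasses counting, for algebraic
# checks of downstream operations)
valueProfile <- function(grid, values, sampleId = "inj", gcCorrected = TRUE) {
  ua <- which(cfScreen:::autosomalUsable(grid))
  values[ua] <- values[ua] / sum(values[ua])
  methods::new("SampleProfile",
    sampleId = sampleId, grid = grid,
    counts = rep(0, nBins(grid)), values = values,
    totalReads = 0, normalized = TRUE, gcCorrected = gcCorrected
  )
}

# full-size shared fixtures (default genome, 1 Mb grid, 50-sample panel),
# built once per test run
.fx <- new.env(parent = emptyenv())
fullFixtures <- function() {
  if (is.null(.fx$grid)) {
    .fx$genome <- defaultGenome()
    .fx$grid <- makeDefaultGrid(.fx$genome, 1e6)
    .fx$panel <- preparePanel(simulatePanel(.fx$grid, 50, seed = 11))
    .fx$index <- buildReferenceIndex(.fx$panel, k = 100)
    .fx$chromStats <- panelChromStats(.fx$panel)
  }
  .fx
}

## ---- independent brute-force oracles --------------------------------------

# exhaustive reference-bin search: V is samples x bins, chrom per bin.
# refIdx comes from all-panel distances (used for scoring new samples);
# mu/sigma are leave-one-out: held-out sample s gets references chosen on
# the distances computed without s.
bruteRefIndex <- function(V, chrom, k, excludeSameChrom = TRUE) {
  nb <- ncol(V); S <- nrow(V)
  elig <- function(i) {
    ok <- rep(TRUE, nb)
    ok[i] <- FALSE
    ok[chrom == "X"] <- FALSE
    if (excludeSameChrom) ok[chrom == chrom[i]] <- FALSE
    ok
  }
  kSmallest <- function(d) order(d, seq_along(d))[seq_len(k)]
  refIdx <- matrix(0L, nrow = k, ncol = nb)
  R <- matrix(0, nrow = S, ncol = nb)
  for (i in seq_len(nb)) {
    ok <- elig(i)
    d <- rep(Inf, nb)
    for (j in which(ok)) d[j] <- sum((V[, i] - V[, j])^2)
    refIdx[, i] <- kSmallest(d)
    for (s in seq_len(S)) {
      ds <- rep(Inf, nb)
      for (j in which(ok)) ds[j] <- sum((V[-s, i] - V[-s, j])^2)
      refs <- kSmallest(ds)
      R[s, i] <- V[s, i] / mean(V[s, refs])
    }
  }
  mu <- colMeans(R)
  sigma <- pmax(apply(R, 2, stats::sd), 1e-4 * mu)
  list(refIdx = refIdx, mu = mu, sigma = sigma)
}

# direct window sums per chromosome
bruteWindow <- function(z, chrom, w) {
  half <- (w - 1) / 2
  Z <- numeric(length(z))
  for (i in seq_along(z)) {
    # window positions counted along the chromosome's own bin axis
    ci <- which(chrom == chrom[i])
    p <- match(i, ci)
    win <- ci[max(p - half, 1):min(p + half, length(ci))]
    Z[i] <- sum(z[win]) / sqrt(length(win))
  }
  Z
}

# direct run-merging segmentation over (chrom, start0, end0, Z)
bruteSegments <- function(chrom, st0, en0, Z, thr, gap) {
  out <- list()
  for (ch in unique(chrom)) {
    ix <- which(chrom == ch)
    marked <- ix[abs(Z[ix]) >= thr]
    while (length(marked)) {
      run <- marked[1]
      marked <- marked[-1]
      repeat {
        if (!length(marked)) break
        nxt <- marked[1]
        between <- ix[ix > run[length(run)] & ix < nxt]
        nUnmarked <- sum(abs(Z[between]) < thr)
        sameSign <- sign(Z[nxt]) == sign(Z[run[1]])
        contiguousGap <- length(between) == nUnmarked && nUnmarked <= gap
        if (sameSign && contiguousGap) {
          run <- c(run, nxt); marked <- marked[-1]
        } else break
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = st0[run[1]], end = en0[run[length(run)]],
        direction = if (Z[run[1]] > 0) "gain" else "loss",
        meanZ = mean(Z[run]), nBins = length(run)
      )
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# Clopper-Pearson bounds by bisection on the binomial tail (no qbeta)
bruteCPBounds <- function(x, n, level = 0.95) {
  alpha <- 1 - level
  bis <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  lower <- if (x == 0) 0 else
    bis(function(p) stats::pbinom(x - 1, n, p, lower.tail = FALSE) - alpha / 2, 0, 1)
  upper <- if (x == n) 1 else
    bis(function(p) alpha / 2 - stats::pbinom(x, n, p), 0, 1)
  c(lower, upper) * 100
}

# GRanges segment helper for constructing inputs
makeSegments <- function(chrom, start0, end0, direction, meanZ = NULL) {
  if (is.null(meanZ)) meanZ <- ifelse(direction == "gain", 5, -5)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
  S4Vectors::mcols(gr)$direction <- direction
  S4Vectors::mcols(gr)$meanZ <- meanZ
  S4Vectors::mcols(gr)$nBins <- as.integer((end0 - start0) / 1e6)
  S4Vectors::mcols(gr)$sizeMb <- (end0 - start0) / 1e6
  gr
}

# ZProfile with an injected windowed track, for segmentation tests
windowedZProfile <- function(grid, Z, sampleId = "inj") {
  use <- which(cfScreen:::usableBins(grid))
  methods::new("ZProfile",
    sampleId = sampleId, grid = grid, usableIdx = as.integer(use),
    z = rep(0, length(use)), zWindowed = Z, window = 7L
  )
}
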