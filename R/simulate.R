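## Synthetic cfDNA cohort generator.
##
## Count model per sample s and usable bin i:
##   weight  w_i = m_i * max(1 + slope_s * (gc_i - gcRef), gcFloor) * d_i
##   d_i     = 1 + tf * (c_i - 2) / 2   (tumor dilution; c_i = truth copy)
##   p_i     = w_i / sum(w)             (over usable bins)
##   count_i ~ NegBin(mu = N_s * p_i, size = dispersion)
## with m_i = exp(eta_i), eta_i ~ N(0, baselineSd^2) fixed per grid, N_s
## uniform on [readsMin, readsMax]. Counts are drawn as
## qnbinom(u_i, ...) from one uniform stream so a fixed seed yields a
## shared randomness stream across parameter changes (e.g. read depth).

#' Construct simulation parameters
#'
#' Defaults emulate shallow-WGS NIPT runs: 18-28 M single-end reads per
#' sample (about 0.2-0.3x coverage at 36 bp), a mild sample-specific linear
#' GC bias, ~10 % log-normal bin-to-bin baseline variation, and
#' negative-binomial overdispersion (size 1000) beyond Poisson.
#'
#' @param readsMin,readsMax total-read draw bounds (default 18e6 / 28e6).
#' @param gcSlopeSd sd of the per-sample GC bias slope (default 0.5).
#' @param gcRef GC fraction with bias factor 1 (default 0.41).
#' @param gcFloor floor of the GC bias factor (default 0.1).
#' @param baselineSd sd of per-bin log baseline weights (default 0.1).
#' @param dispersion negative-binomial size (default 1000); larger is
#'   closer to Poisson.
#' @param baselineSeed seed fixing the per-grid baseline weights (default
#'   104729); samples on the same grid share the same baseline.
#' @return a [SimParams-class].
#' @examples
#' simParams(dispersion = 500)
#' @export
simParams <- function(readsMin = 18e6, readsMax = 28e6, gcSlopeSd = 0.5,
                      gcRef = 0.41, gcFloor = 0.1, baselineSd = 0.1,
                      dispersion = 1000, baselineSeed = 104729L) {
  new("SimParams",
    readsMin = readsMin, readsMax = readsMax, gcSlopeSd = gcSlopeSd,
    gcRef = gcRef, gcFloor = gcFloor, baselineSd = baselineSd,
    dispersion = dispersion, baselineSeed = as.integer(baselineSeed)
  )
}

## run expr under a given seed, restoring the caller's RNG state
.withSeed <- function(seed, fun) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fun()
}

## per-grid log-normal baseline weights, fixed by params@baselineSeed
.binBaseline <- function(grid, params) {
  .withSeed(params@baselineSeed, function() {
    exp(stats::rnorm(nBins(grid), mean = 0, sd = params@baselineSd))
  })
}

## per-bin copy number implied by a truth profile (majority-overlap rule:
## a bin takes an event's copy number iff the event covers > half the bin)
.binCopy <- function(grid, truth) {
  copy <- rep(2, nBins(grid))
  ev <- truth@events
  if (!nrow(ev)) return(copy)
  evGr <- GenomicRanges::GRanges(ev$chrom, IRanges::IRanges(ev$start + 1, ev$end))
  hits <- GenomicRanges::findOverlaps(grid@bins, evGr)
  if (!length(hits)) return(copy)
  ov <- GenomicRanges::pintersect(
    grid@bins[S4Vectors::queryHits(hits)], evGr[S4Vectors::subjectHits(hits)]
  )
  frac <- GenomicRanges::width(ov) / GenomicRanges::width(grid@bins[S4Vectors::queryHits(hits)])
  keep <- frac > 0.5
  copy[S4Vectors::queryHits(hits)[keep]] <- ev$copy[S4Vectors::subjectHits(hits)[keep]]
  copy
}

## core sampler; copyMult multiplies the expected bin weights
.simulateOne <- function(grid, params, copyMult, seed, sampleId) {
  base <- .binBaseline(grid, params)
  gc <- .gridGC(grid)
  use <- usableBins(grid)
  counts <- .withSeed(seed, function() {
    N <- round(stats::runif(1, params@readsMin, params@readsMax))
    slope <- stats::rnorm(1, 0, params@gcSlopeSd)
    gcFac <- pmax(1 + slope * (gc - params@gcRef), params@gcFloor)
    w <- base * gcFac * copyMult
    w[!use] <- 0
    p <- w[use] / sum(w[use])
    mu <- N * p
    u <- stats::runif(sum(use))
    out <- numeric(length(w))
    out[use] <- stats::qnbinom(u, size = params@dispersion, mu = mu)
    out
  })
  SampleProfile(sampleId, grid, counts)
}

#' Simulate one copy-neutral sample
#'
#' Draws a single euploid shallow-WGS profile from the count model. A fixed
#' seed fully determines the output.
#'
#' @param grid a [BinGrid-class].
#' @param params a [SimParams-class].
#' @param seed integer seed for this sample.
#' @param sampleId sample identifier.
#' @return a raw-count [SampleProfile-class].
#' @seealso [simulatePanel()], [simulateCase()]
#' @export
simulateSample <- function(grid, params = simParams(), seed = 1L,
                           sampleId = "sample") {
  .simulateOne(grid, params, rep(1, nBins(grid)), seed, sampleId)
}

#' Simulate a copy-neutral reference panel
#'
#' Generates `nSamples` independent euploid samples; per-sample seeds are
#' derived deterministically from `seed`.
#'
#' @param grid a [BinGrid-class].
#' @param nSamples number of panel samples (>= 2; a warning is issued below
#'   10, where panel ratio statistics become unstable).
#' @param params a [SimParams-class].
#' @param seed master seed.
#' @param idPrefix sample-id prefix (default `"panel"`).
#' @return a list of raw-count [SampleProfile-class] objects.
#' @export
simulatePanel <- function(grid, nSamples, params = simParams(), seed = 1L,
                          idPrefix = "panel") {
  if (nSamples < 2)
    stop("a reference panel needs at least 2 samples")
  if (nSamples < 10)
    warning("panels below 10 samples give unstable reference statistics")
  seeds <- .withSeed(seed, function() sample.int(.Machine$integer.max, nSamples))
  lapply(seq_len(nSamples), function(s) {
    .simulateOne(grid, params, rep(1, nBins(grid)), seeds[s],
                 sprintf("%s_%02d", idPrefix, s))
  })
}

#' Draw a tumor copy-number truth profile
#'
#' Each catalog record is included independently with probability equal to
#' its tumor frequency (gain: copy 3, loss: copy 1 on the full arm). On top,
#' `Poisson(focalRate)` focal events of length uniform on 1-10 Mb are placed
#' uniformly on the genome with copy number drawn from \{0, 1, 3, 4\}
#' (mostly single-copy changes). Overlaps are resolved by keeping the
#' earlier-drawn event: catalog events in catalog order, then focal events
#' in draw order.
#'
#' @param catalog a non-empty [CNVCatalog-class].
#' @param genome a [GenomeSpec-class] providing arm boundaries.
#' @param tumorFraction tumor fraction of the simulated case, in `[0,1]`.
#' @param focalRate expected number of focal events (default 3).
#' @param seed integer seed.
#' @return a [TruthProfile-class].
#' @export
drawTumorProfile <- function(catalog, genome, tumorFraction,
                             focalRate = 3, seed = 1L) {
  stopifnot(is(catalog, "CNVCatalog"), is(genome, "GenomeSpec"))
  tab <- catalogTable(catalog)
  if (!nrow(tab)) stop("catalog is empty")
  if (tumorFraction < 0 || tumorFraction > 1)
    stop("tumorFraction must lie in [0, 1]")
  ab <- armBounds(genome)
  ev <- .withSeed(seed, function() {
    take <- stats::runif(nrow(tab)) < tab$frequency
    rows <- list()
    for (j in which(take)) {
      a <- ab[ab$arm == tab$arm[j], ]
      if (!nrow(a)) next  # catalog arm absent from this genome
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = a$chrom, start = a$start, end = a$end,
        copy = if (tab$direction[j] == "gain") 3 else 1,
        origin = "catalog", stringsAsFactors = FALSE
      )
    }
    nFocal <- stats::rpois(1, focalRate)
    lens <- chromLengths(genome)
    for (f in seq_len(nFocal)) {
      chrom <- sample(names(lens), 1L, prob = lens / sum(lens))
      size <- stats::runif(1, 1e6, 10e6)
      start <- floor(stats::runif(1, 0, max(lens[[chrom]] - size, 1)))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = start, end = floor(start + size),
        copy = sample(c(0, 1, 3, 4), 1L, prob = c(0.05, 0.45, 0.45, 0.05)),
        origin = "focal", stringsAsFactors = FALSE
      )
    }
    if (!length(rows))
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), copy = numeric(),
                        origin = character(), stringsAsFactors = FALSE))
    all <- do.call(rbind, rows)
    ## keep earlier-drawn events when overlapping
    keep <- rep(TRUE, nrow(all))
    for (j in seq_len(nrow(all))[-1]) {
      prior <- all[seq_len(j - 1L), ][keep[seq_len(j - 1L)], , drop = FALSE]
      clash <- prior$chrom == all$chrom[j] &
        prior$start < all$end[j] & all$start[j] < prior$end
      if (any(clash)) keep[j] <- FALSE
    }
    all[keep, , drop = FALSE]
  })
  rownames(ev) <- NULL
  new("TruthProfile", tumorFraction = tumorFraction, events = ev)
}

#' Simulate a case sample carrying a tumor truth profile
#'
#' Expected bin weights are multiplied by the linear plasma mixture factor
#' `1 + tf * (c - 2) / 2`, where `c` is the truth copy number covering the
#' bin (2 where no event; boundary bins take the copy number covering the
#' majority of the bin), then renormalized and counted exactly as in
#' [simulateSample()]. With `tf = 0` the output is identical to a
#' copy-neutral sample drawn with the same seed.
#'
#' @param grid a [BinGrid-class].
#' @param truth a [TruthProfile-class].
#' @param params a [SimParams-class].
#' @param seed integer seed.
#' @param sampleId sample identifier.
#' @return a raw-count [SampleProfile-class].
#' @export
simulateCase <- function(grid, truth, params = simParams(), seed = 1L,
                         sampleId = "case") {
  stopifnot(is(truth, "TruthProfile"))
  tf <- truth@tumorFraction
  if (tf < 0 || tf > 1) stop("tumor fraction must lie in [0, 1]")
  copy <- .binCopy(grid, truth)
  mult <- 1 + tf * (copy - 2) / 2
  .simulateOne(grid, params, mult, seed, sampleId)
}

#' Simulate and write a full case/control cohort to disk
#'
#' Writes a reference panel, case and control count files, a cohort manifest
#' (`sample_id`, `group`, `stage_label`, `tumor_fraction`, `counts_path`), a
#' truth JSON and the bin grid under `outDir`. The default configuration
#' mirrors the screening study design: 16 early + 16 advanced cases and 32
#' copy-neutral controls, plus a 50-sample panel. Identical `config` and
#' seed give byte-identical output.
#'
#' @param config named list (or path to a YAML file) overriding any of:
#'   `n_early` (16), `n_advanced` (16), `n_controls` (32), `panel_n` (50),
#'   `tf_early` (range, default `c(0.02, 0.15)`), `tf_advanced` (default
#'   `c(0.05, 0.30)`), `focal_rate` (3), `bin_size` (1e6), `seed` (1).
#' @param outDir output directory (created; error if it exists unless
#'   `overwrite`).
#' @param genome a [GenomeSpec-class] (default [defaultGenome()]).
#' @param params a [SimParams-class].
#' @param catalog a [CNVCatalog-class] for truth draws (default
#'   [defaultCatalog()]).
#' @param overwrite allow writing into an existing directory.
#' @return invisibly, a list with the manifest data.frame, truth profiles
#'   and file paths.
#' @export
simulateCohort <- function(config = list(), outDir, genome = defaultGenome(),
                           params = simParams(), catalog = defaultCatalog(),
                           overwrite = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- list(n_early = 16L, n_advanced = 16L, n_controls = 32L,
              panel_n = 50L, tf_early = c(0.02, 0.15),
              tf_advanced = c(0.05, 0.30), focal_rate = 3,
              bin_size = 1e6, seed = 1L)
  cfg <- utils::modifyList(def, config)
  if (dir.exists(outDir) && !overwrite)
    stop("output directory exists: ", outDir, " (set overwrite = TRUE)")
  dir.create(file.path(outDir, "panel"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outDir, "counts"), showWarnings = FALSE)

  grid <- makeDefaultGrid(genome, cfg$bin_size)
  writeBinGrid(grid, file.path(outDir, "grid.tsv"))

  panel <- simulatePanel(grid, cfg$panel_n, params, seed = cfg$seed)
  for (p in panel)
    writeBinCounts(p, file.path(outDir, "panel", paste0(sampleId(p), ".tsv")))

  groups <- c(rep("early", cfg$n_early), rep("advanced", cfg$n_advanced),
              rep("control", cfg$n_controls))
  n <- length(groups)
  draws <- .withSeed(cfg$seed + 1L, function() {
    list(
      seeds = sample.int(.Machine$integer.max, 2L * n),
      u = stats::runif(n)
    )
  })
  manifest <- data.frame(
    sample_id = sprintf("sim_%03d", seq_len(n)), group = groups,
    stage_label = groups, tumor_fraction = 0,
    counts_path = file.path("counts", sprintf("sim_%03d.tsv", seq_len(n))),
    stringsAsFactors = FALSE
  )
  manifest$group <- ifelse(groups == "control", "control", "case")
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    if (groups[i] == "control") {
      tf <- 0
      truths[[i]] <- new("TruthProfile", tumorFraction = 0,
                         events = data.frame(chrom = character(),
                                             start = numeric(), end = numeric(),
                                             copy = numeric(), origin = character(),
                                             stringsAsFactors = FALSE))
      prof <- simulateSample(grid, params, seed = draws$seeds[i],
                             sampleId = manifest$sample_id[i])
    } else {
      rng <- if (groups[i] == "early") cfg$tf_early else cfg$tf_advanced
      tf <- rng[1] + draws$u[i] * (rng[2] - rng[1])
      truths[[i]] <- drawTumorProfile(catalog, genome, tf,
                                      focalRate = cfg$focal_rate,
                                      seed = draws$seeds[n + i])
      prof <- simulateCase(grid, truths[[i]], params, seed = draws$seeds[i],
                           sampleId = manifest$sample_id[i])
    }
    manifest$tumor_fraction[i] <- tf
    writeBinCounts(prof, file.path(outDir, manifest$counts_path[i]))
  }
  utils::write.table(manifest, file.path(outDir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truthJson <- lapply(seq_len(n), function(i) list(
    sample_id = manifest$sample_id[i],
    tumor_fraction = truths[[i]]@tumorFraction,
    events = truths[[i]]@events[, c("chrom", "start", "end", "copy")]
  ))
  jsonlite::write_json(truthJson, file.path(outDir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, truths = truths, dir = outDir,
                 grid = grid))
}
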