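# Synthetic cohort generator: determinism, count model, tumor dilution.

test_that("a fixed seed fully determines simulated counts", {
  grid <- toyGrid()
  a <- simulateSample(grid, seed = 42)
  b <- simulateSample(grid, seed = 42)
  expect_identical(rawCounts(a), rawCounts(b))
  c <- simulateSample(grid, seed = 43)
  expect_false(identical(rawCounts(a), rawCounts(c)))
})

test_that("per-sample totals stay near the configured read range", {
  grid <- toyGrid()
  suppressWarnings(panel <- simulatePanel(grid, 8, seed = 7))
  totals <- vapply(panel, totalReads, numeric(1))
  expect_true(all(totals >= 18e6 * 0.9))
  expect_true(all(totals <= 28e6 * 1.1))
  expect_error(simulatePanel(grid, 1, seed = 1), "at least 2")
  expect_warning(simulatePanel(grid, 3, seed = 1), "unstable")
})

test_that("large dispersion approaches the Poisson variance/mean limit", {
  grid <- miniGrid(1, 20)
  fixed <- function(r) simParams(readsMin = 1e6, readsMax = 1e6, gcSlopeSd = 0,
                                 dispersion = r)
  binAt <- function(r) {
    vapply(1:500, function(i)
      rawCounts(simulateSample(grid, fixed(r), seed = 100 + i))[10], numeric(1))
  }
  nearPois <- binAt(1e9)
  expect_gt(var(nearPois) / mean(nearPois), 0.85)
  expect_lt(var(nearPois) / mean(nearPois), 1.15)
  # at the shallow-WGS default the same bin is clearly overdispersed
  over <- binAt(100)
  expect_gt(var(over) / mean(over), 10)
})

test_that("tumor truth profiles follow catalog frequencies and overlap rules", {
  genome <- toyGenome()
  always <- CNVCatalog("1q", "gain", 0.01, 1.0)
  for (s in 1:5) {
    tp <- drawTumorProfile(always, genome, 0.2, focalRate = 0, seed = s)
    ev <- truthEvents(tp)
    expect_equal(nrow(ev), 1L)
    expect_equal(ev$copy, 3)
    expect_equal(ev$start, 25e6)  # full q arm
    expect_equal(ev$end, 60e6)
  }
  never <- CNVCatalog(c("1q", "2p"), c("gain", "loss"), c(0.01, 0.01), c(0, 0))
  tp0 <- drawTumorProfile(never, genome, 0.2, focalRate = 0, seed = 1)
  expect_equal(nrow(truthEvents(tp0)), 0L)

  # inclusion frequency of the 8q gain matches its catalog frequency
  cat <- defaultCatalog()
  f8q <- catalogTable(cat)$frequency[catalogTable(cat)$arm == "8q" &
                                     catalogTable(cat)$direction == "gain"]
  hits <- vapply(1:1000, function(s) {
    ev <- truthEvents(drawTumorProfile(cat, defaultGenome(), 0.1,
                                       focalRate = 0, seed = s))
    any(ev$chrom == "8" & ev$copy == 3 & ev$start == 45.6e6)
  }, logical(1))
  se <- sqrt(f8q * (1 - f8q) / 1000)
  expect_lt(abs(mean(hits) - f8q), 3 * se)

  # events never overlap, whatever the seed
  for (s in 1:20) {
    ev <- truthEvents(drawTumorProfile(cat, defaultGenome(), 0.3,
                                       focalRate = 5, seed = s))
    expect_no_error(methods::validObject(
      methods::new("TruthProfile", tumorFraction = 0.3, events = ev)))
  }
  expect_error(drawTumorProfile(cat, genome, 1.5), "\\[0, 1\\]")
})

test_that("tf = 0 cases are identical to copy-neutral samples on the same seed", {
  grid <- toyGrid()
  truth0 <- drawTumorProfile(CNVCatalog("1q", "gain", 0.01, 1.0), toyGenome(),
                             tumorFraction = 0, focalRate = 0, seed = 5)
  case <- simulateCase(grid, truth0, seed = 77)
  neutral <- simulateSample(grid, seed = 77)
  expect_identical(rawCounts(case), rawCounts(neutral))
})

test_that("tumor fraction dilutes arm signal by the linear mixture factor", {
  grid <- toyGrid()
  genome <- toyGenome()
  # copy-3 gain of chromosome 2q (30 bins) at tf = 0.2: expected relative
  # elevation 1 + 0.2 * (3 - 2) / 2 = 1.10 before renormalization
  truth <- drawTumorProfile(CNVCatalog("2q", "gain", 0.01, 1.0), genome,
                            tumorFraction = 0.2, focalRate = 0, seed = 1)
  arm <- cfScreen:::.gridChrom(grid) == "2" & cfScreen:::.gridStart0(grid) >= 20e6
  suppressWarnings(panel <- simulatePanel(grid, 5, seed = 200))
  panelVals <- rowMeans(vapply(preparePanel(panel),
                               function(p) normValues(p), numeric(nBins(grid))))
  share <- sum(panelVals[arm])
  expected <- 1.10 / (1 + 0.10 * share)  # renormalization over usable bins
  ratios <- vapply(1:200, function(i) {
    v <- normValues(gcCorrect(normalizeCounts(
      simulateCase(grid, truth, seed = 300 + i))))
    mean(v[arm] / panelVals[arm])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - expected), 0.01)

  # tf = 1 whole-arm copy 4 doubles the expected weight before renormalization
  truth4 <- methods::new("TruthProfile", tumorFraction = 1,
    events = data.frame(chrom = "2", start = 20e6, end = 50e6, copy = 4,
                        origin = "catalog"))
  mult <- 1 + 1 * (cfScreen:::.binCopy(grid, truth4) - 2) / 2
  expect_true(all(mult[arm] == 2))
  expect_true(all(mult[!arm] == 1))
})

test_that("boundary bins take the majority-overlap copy number", {
  grid <- miniGrid(1, 10)
  # event covers 60 % of bin 3 and 40 % of bin 6
  truth <- methods::new("TruthProfile", tumorFraction = 0.5,
    events = data.frame(chrom = "1", start = 2.4e6, end = 5.4e6, copy = 3,
                        origin = "focal"))
  copy <- cfScreen:::.binCopy(grid, truth)
  expect_equal(copy, c(2, 2, 3, 3, 3, 2, 2, 2, 2, 2))
})

test_that("cohort simulation writes a complete, reproducible directory", {
  genome <- toyGenome()
  cfg <- list(n_early = 2, n_advanced = 0, n_controls = 2, panel_n = 2,
              bin_size = 1e6, seed = 9)
  cat <- defaultCatalog()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  suppressWarnings({
    r1 <- simulateCohort(cfg, file.path(d1, "c"), genome = genome,
                         catalog = cat)
    r2 <- simulateCohort(cfg, file.path(d2, "c"), genome = genome,
                         catalog = cat)
  })
  expect_equal(nrow(r1$manifest), 4L)
  expect_equal(sum(r1$manifest$group == "control"), 2L)
  expect_true(all(file.exists(file.path(d1, "c", r1$manifest$counts_path))))
  expect_length(list.files(file.path(d1, "c", "panel")), 2L)
  expect_true(all(r1$manifest$tumor_fraction[r1$manifest$group == "case"] >= 0.02))
  expect_equal(r1$manifest$tumor_fraction[r1$manifest$group == "control"], c(0, 0))

  # byte-identical reruns
  for (f in c("manifest.tsv", "truth.json", "grid.tsv",
              r1$manifest$counts_path[1])) {
    expect_identical(readLines(file.path(d1, "c", f)),
                     readLines(file.path(d2, "c", f)))
  }
  # refusing to clobber an existing directory
  expect_error(
    suppressWarnings(simulateCohort(cfg, file.path(d1, "c"), genome = genome,
                                    catalog = cat)),
    "exists")

  # the same configuration supplied as a YAML file gives the same cohort
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  suppressWarnings(r3 <- simulateCohort(yml, file.path(d1, "y"),
                                        genome = genome, catalog = cat))
  expect_identical(readLines(file.path(d1, "y", "manifest.tsv")),
                   readLines(file.path(d1, "c", "manifest.tsv")))
})
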