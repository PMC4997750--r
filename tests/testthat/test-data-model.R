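# Data model and on-disk formats.

test_that("bin grids parse, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tgc",
               "1\t0\t1000000\t0.41",
               "1\t1000000\t2000000\t0.44"), path)
  grid <- loadBinGrid(path)
  expect_equal(nBins(grid), 2L)
  expect_equal(binSize(grid), 1e6)
  expect_equal(S4Vectors::mcols(binRanges(grid))$gc, c(0.41, 0.44))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tgc", "1\t2000000\t1000000\t0.41"), bad)
  expect_error(loadBinGrid(bad), "end <= start")
  expect_error(loadBinGrid("/nonexistent/grid.tsv"), "no such file")

  # overlapping bins rejected
  ovl <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tgc",
               "1\t0\t1000000\t0.41", "1\t500000\t1500000\t0.41"), ovl)
  expect_error(loadBinGrid(ovl), "overlap")

  rt <- withr::local_tempfile(fileext = ".tsv")
  full <- toyGrid()
  writeBinGrid(full, rt)
  back <- loadBinGrid(rt)
  expect_identical(cfScreen:::.gridChrom(back), cfScreen:::.gridChrom(full))
  expect_identical(cfScreen:::.gridStart0(back), cfScreen:::.gridStart0(full))
  expect_identical(cfScreen:::.gridEnd0(back), cfScreen:::.gridEnd0(full))
  expect_equal(cfScreen:::.gridGC(back), cfScreen:::.gridGC(full))
  expect_identical(cfScreen:::usableBins(back), cfScreen:::usableBins(full))
})

test_that("genome tiling keeps and flags trailing partial bins", {
  g <- GenomeSpec("1", 10e6, 5e6)
  expect_equal(nBins(makeDefaultGrid(g, 1e6)), 10L)

  g2 <- GenomeSpec("1", 10.4e6, 5e6)
  grid2 <- makeDefaultGrid(g2, 1e6)
  expect_equal(nBins(grid2), 11L)
  expect_false(cfScreen:::usableBins(grid2)[11])
  expect_true(all(cfScreen:::usableBins(grid2)[1:10]))

  # a trailing bin of at least half the bin size stays usable
  g3 <- GenomeSpec("1", 10.6e6, 5e6)
  expect_true(all(cfScreen:::usableBins(makeDefaultGrid(g3, 1e6))))

  expect_error(makeDefaultGrid(g, -1), "positive")
  expect_error(makeDefaultGrid(g, 5e4), "100 kb")

  # default genome at 1 Mb: about 2,900 usable autosomal bins
  grid <- fullFixtures()$grid
  nAuto <- sum(cfScreen:::autosomalUsable(grid))
  expect_gt(nAuto, 2700)
  expect_lt(nAuto, 3100)
})

test_that("bin-count files attach to a grid and round-trip", {
  grid <- miniGrid(1, 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tgc\tcount",
               "1\t0\t1000000\t0.35\t100",
               "1\t1000000\t2000000\t0.42\t50",
               "1\t2000000\t3000000\t0.5\t25"), path)
  prof <- readBinCounts(path, grid, sampleId = "s1")
  expect_s4_class(prof, "SampleProfile")
  expect_equal(totalReads(prof), 175)
  expect_equal(rawCounts(prof), c(100, 50, 25))

  # extra bin: count of rows no longer matches
  extra <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(readLines(path), "1\t3000000\t4000000\t0.4\t10"), extra)
  expect_error(readBinCounts(extra, grid), "4 bins but grid has 3")

  # shifted coordinates: first mismatching bin is named
  shift <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tgc\tcount",
               "1\t0\t1000000\t0.35\t100",
               "1\t1500000\t2500000\t0.42\t50",
               "1\t2500000\t3500000\t0.5\t25"), shift)
  expect_error(readBinCounts(shift, grid), "bin 2 mismatches")

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tgc\tcount",
               "1\t0\t1000000\t0.35\t-5",
               "1\t1000000\t2000000\t0.42\t50",
               "1\t2000000\t3000000\t0.5\t25"), neg)
  expect_error(readBinCounts(neg, grid), "negative count at bin 1")

  # simulated sample round-trips losslessly
  sim <- simulateSample(toyGrid(), seed = 3)
  rt <- withr::local_tempfile(fileext = ".tsv")
  writeBinCounts(sim, rt)
  back <- readBinCounts(rt, toyGrid())
  expect_identical(rawCounts(back), rawCounts(sim))
})

test_that("catalog files validate and the bundled catalog has the documented shape", {
  cat <- defaultCatalog()
  tab <- catalogTable(cat)
  expect_equal(sum(tab$direction == "gain"), 8L)
  expect_equal(sum(tab$direction == "loss"), 22L)
  # 5 of 8 gains and 18 of 22 losses above 50 % frequency
  expect_equal(sum(tab$direction == "gain" & tab$frequency > 0.5), 5L)
  expect_equal(sum(tab$direction == "loss" & tab$frequency > 0.5), 18L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("arm\tdirection\tq_value\tfrequency", "3q\tgain\t0.01\t1.2"), bad)
  expect_error(loadCatalog(bad), "frequency")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("arm\tdirection\tq_value\tfrequency",
               "3q\tgain\t0.01\t0.7", "3q\tgain\t0.02\t0.6"), dup)
  expect_error(loadCatalog(dup), "unique")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("arm\tdirection\tq_value\tfrequency", empty)
  ecat <- loadCatalog(empty)
  expect_equal(nrow(catalogTable(ecat)), 0L)
  expect_equal(classifyCNV("3q", "gain", ecat), "non_specific")
})

test_that("segment BED output is lossless for coordinates and sizes", {
  segs <- makeSegments("3", 90e6, 110e6, "gain", meanZ = 6.2)
  path <- withr::local_tempfile(fileext = ".bed")
  writeSegments(segs, path)
  lines <- readLines(path)
  expect_length(lines, 2L)
  fields <- strsplit(lines[2], "\t")[[1]]
  expect_equal(fields[1:6], c("3", "90000000", "110000000", "gain", "6", "."))
  expect_equal(as.numeric(fields[7]), 20.0)

  back <- readSegments(path)
  expect_equal(as.character(GenomicRanges::seqnames(back)), "3")
  expect_equal(GenomicRanges::start(back) - 1, 90e6)
  expect_equal(GenomicRanges::end(back), 110e6)
  expect_equal(S4Vectors::mcols(back)$sizeMb, 20.0)
  expect_equal(S4Vectors::mcols(back)$direction, "gain")

  # empty segment list: header-only file
  epath <- withr::local_tempfile(fileext = ".bed")
  writeSegments(cfScreen:::.emptySegments(), epath)
  expect_length(readLines(epath), 1L)
  expect_length(readSegments(epath), 0L)
})

test_that("class invariants reject malformed objects", {
  expect_error(GenomeSpec("1", 10e6, 11e6), "centromere")
  expect_error(GenomeSpec(c("1", "1"), c(1e6, 2e6), c(5e5, 1e6)), "unique")
  expect_error(BinGrid("1", 1e6, 1e6, 0.4), "end > start")
  grid <- miniGrid(1, 3)
  expect_error(SampleProfile("s", grid, c(1, 2)), "does not match")
  expect_error(SampleProfile("s", grid, c(-1, 2, 3)), "non-negative")
})
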