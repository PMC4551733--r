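test_that("FragmentMap enforces its invariants", {
  fm <- FragmentMap("m1", c(11, 40, 49))
  expect_equal(mapSpan(fm), 100)
  expect_equal(nFragments(fm), 3L)
  expect_error(FragmentMap("bad", c(10, 0, 5)), "> 0")
  expect_error(FragmentMap("bad", numeric(0)), "at least one fragment")
  expect_error(FragmentMap("bad", c(10, 5), kind = "rmap",
                           gapFlags = c(TRUE, FALSE)), "chromosome")
})

test_that("OMAP files round-trip bit-exactly and reject malformed input", {
  withr::local_seed(42)
  maps <- lapply(1:100, function(k)
    FragmentMap(sprintf("m%03d", k),
                round(runif(sample(3:20, 1), 500, 40000), 2)))
  f <- withr::local_tempfile(fileext = ".omap")
  writeMaps(maps, f)
  back <- readMaps(f)
  expect_equal(length(back), 100L)
  expect_identical(vapply(back, mapId, character(1)),
                   vapply(maps, mapId, character(1)))
  for (k in seq_along(maps))
    expect_equal(fragments(back[[k]]), fragments(maps[[k]]))
  # write(read(f)) is byte-identical
  f2 <- withr::local_tempfile(fileext = ".omap")
  writeMaps(back, f2)
  expect_identical(readLines(f), readLines(f2))

  # gap flags survive the round trip
  chrom <- FragmentMap("c1", c(1e6, 5e5, 2e6), kind = "chromosome",
                       gapFlags = c(FALSE, TRUE, FALSE))
  f3 <- withr::local_tempfile(fileext = ".omap")
  writeMaps(chrom, f3)
  expect_identical(gapFlags(readMaps(f3)[[1]]), c(FALSE, TRUE, FALSE))

  bad <- withr::local_tempfile(fileext = ".omap")
  writeLines(c("m1\tBamHI\t10 20", "m2\tBamHI\t10 0 30"), bad)
  expect_error(readMaps(bad), "line 2")
  dup <- withr::local_tempfile(fileext = ".omap")
  writeLines(c("m1\tBamHI\t10 20", "m1\tBamHI\t30"), dup)
  expect_error(readMaps(dup), "duplicate")
})

test_that("filtering is inclusive at the boundary and identity at zero", {
  set <- RmapSet(list(FragmentMap("a", 250e3), FragmentMap("b", 300e3),
                      FragmentMap("c", 400e3)))
  kept <- filterRmaps(set, 300e3)
  expect_identical(rmapIds(kept), c("b", "c"))
  expect_identical(rmapIds(filterRmaps(set, 0)), c("a", "b", "c"))
})

test_that("filtering matches brute-force enumeration on simulated lengths", {
  withr::local_seed(7)
  spans <- pmax(rnorm(1000, 4e5, 6e4), 1.5e5)
  set <- RmapSet(lapply(seq_along(spans), function(k)
    FragmentMap(sprintf("r%04d", k), spans[k])))
  kept <- filterRmaps(set, 3e5)
  expect_equal(length(kept), sum(spans >= 3e5))
})

test_that("dataset summaries follow total-mass arithmetic", {
  one <- RmapSet(list(FragmentMap("a", 3e5)))
  s <- summarizeDataset(one, genomeSize = 3e5)
  expect_equal(s$meanLengthKb, 300)
  expect_equal(s$foldCoverage, 1)
  expect_error(summarizeDataset(RmapSet(list())), "empty")

  withr::local_seed(11)
  maps <- lapply(1:10, function(k)
    FragmentMap(sprintf("r%d", k), runif(5, 1e4, 1e5)))
  s10 <- summarizeDataset(RmapSet(maps))
  expect_equal(s10$totalMassMb,
               sum(vapply(maps, mapSpan, numeric(1))) / 1e6)
  # permutation invariance
  s10b <- summarizeDataset(RmapSet(rev(maps)))
  expect_equal(s10$totalMassMb, s10b$totalMassMb)
  expect_equal(s10$meanLengthKb, s10b$meanLengthKb)
})

test_that("the published dataset totals reproduce the printed mean length", {
  ds <- omtkFixture("dataset_summary")
  expect_equal(round(ds$total_mass_mb * 1000 / ds$n_rmaps, 2), 397.49)
})
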