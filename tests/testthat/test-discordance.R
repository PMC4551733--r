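test_that("single unmatched cuts are classified EC/MC by construction", {
  # one extra sequence cut at a known coordinate, inside a matched context:
  # [ctx..., 30k, 20k, 50k, ...ctx] vs [ctx..., 30k, 70k, ...ctx]
  withr::local_seed(303)
  ctxL <- runif(16, 6e3, 2.4e4)
  ctxR <- runif(16, 6e3, 2.4e4)
  seqm <- FragmentMap("seq", c(ctxL, 30e3, 20e3, 50e3, ctxR),
                      kind = "insilico")
  optm <- FragmentMap("opt", c(ctxL, 30e3, 70e3, ctxR), kind = "chromosome")
  d <- callDiscordances(optm, seqm)
  expect_equal(nrow(d), 1L)
  expect_equal(d$category, "EC")
  expect_equal(d$seqStart, sum(ctxL) + 50e3, tolerance = 1)

  # converse: the optical side carries the extra cut
  d2 <- callDiscordances(seqm, optm)
  expect_equal(d2$category, "MC")
})

test_that("a matched block with a large size anomaly is a clean indel", {
  withr::local_seed(304)
  ctxL <- runif(16, 6e3, 2.4e4)
  ctxR <- runif(16, 6e3, 2.4e4)
  seqm <- FragmentMap("seq", c(ctxL, 30e3, 100e3, 50e3, ctxR))
  optm <- FragmentMap("opt", c(ctxL, 30e3, 60e3, 50e3, ctxR),
                      kind = "chromosome")
  d <- callDiscordances(optm, seqm)
  expect_true("DEL" %in% d$category)
  del <- d[d$category == "DEL", ]
  expect_equal(del$sizeDiff[1], 40e3, tolerance = 3e3)
})

test_that("planted events are recovered from a clean optical map", {
  tr <- simulateReference(2e7, seed = 311)
  pl <- plantAssemblyErrors(tr, spec = plantSpec(nPerCategory = 5),
                            seed = 312)
  d <- callDiscordances(tr, pl$map, chrom = "chr1")
  sc <- scoreAgainstLedger(d, pl$ledger)
  expect_gte(sc$recall, 0.9)
  expect_gte(sc$categoryAccuracy, 0.8)
  # EC/MC positions within 5 kb of the ledger
  for (k in which(pl$ledger$category %in% c("EC", "MC"))) {
    hit <- d[d$category == pl$ledger$category[k] &
             abs(d$seqStart - pl$ledger$asmStart[k]) < 5e3, ]
    expect_gte(nrow(hit), 1L)
  }
})

test_that("an unmodified build yields no discordances against its own map", {
  tr <- simulateReference(1e7, seed = 321)
  d <- callDiscordances(tr, tr, chrom = "chr1")
  expect_lte(nrow(d) / 10, 0.1)
})

test_that("large planted inversions and translocations are single IT calls", {
  tr <- simulateReference(2e7, seed = 331)
  spI <- plantSpec(nPerCategory = 0)
  spI$INV <- list(n = 1, size = c(1284e3, 1284e3))
  plI <- plantAssemblyErrors(tr, spec = spI, seed = 332)
  itsI <- callITs(list(chr1_OM = tr), list(chr1 = plI$map))
  expect_equal(nrow(itsI), 1L)
  expect_equal(itsI$subtype, "inversion")
  expect_lt(abs(itsI$seqStart - plI$ledger$asmStart), 3e4)
  expect_gt(itsI$seqEnd - itsI$seqStart, 1e6)

  spT <- plantSpec(nPerCategory = 0)
  spT$TRANS <- list(n = 1, size = c(759e3, 759e3))
  plT <- plantAssemblyErrors(tr, spec = spT, seed = 333)
  itsT <- callITs(list(chr1_OM = tr), list(chr1 = plT$map))
  expect_equal(nrow(itsT), 1L)
  expect_match(itsT$subtype, "translocation|both")

  # unmodified build: zero ITs
  its0 <- callITs(list(chr1_OM = tr), list(chr1 = tr))
  expect_equal(nrow(its0), 0L)
})

test_that("gap intersection counts match a quadratic all-pairs oracle", {
  withr::local_seed(341)
  disc <- data.frame(category = sample(c("EC", "DEL", "COMPLEX"), 60, TRUE),
                     chrom = sample(c("chr1", "chr2"), 60, TRUE),
                     seqStart = runif(60, 0, 1e7))
  disc$seqEnd <- disc$seqStart + runif(60, 0, 5e4)
  gaps <- data.frame(name = sample(c("chr1", "chr2"), 40, TRUE),
                     start = runif(40, 0, 1e7))
  gaps$end <- gaps$start + runif(40, 2e3, 3e4)
  r <- intersectGaps(disc, gaps)
  ovl <- function(a0, a1, b0, b1) a0 < b1 & b0 < a1
  dHit <- vapply(seq_len(nrow(disc)), function(i)
    any(disc$chrom[i] == gaps$name &
        ovl(disc$seqStart[i], disc$seqEnd[i], gaps$start, gaps$end)),
    logical(1))
  gHit <- vapply(seq_len(nrow(gaps)), function(j)
    any(gaps$name[j] == disc$chrom &
        ovl(gaps$start[j], gaps$end[j], disc$seqStart, disc$seqEnd)),
    logical(1))
  expect_equal(r$nDiscIntersecting, sum(dHit))
  expect_equal(r$nGapsIntersected, sum(gHit))
  expect_equal(r$pctGaps, round(100 * sum(gHit) / nrow(gaps), 1))
  # disjoint case
  r0 <- intersectGaps(disc[1, , drop = FALSE],
                      data.frame(name = "chrZ", start = 1, end = 100))
  expect_equal(r0$nDiscIntersecting, 0L)
})

test_that("gap bridging needs a single segment covering both flanks", {
  segments <- data.frame(chrom = "chr1",
                         seqStart = c(0, 6e6), seqEnd = c(5e6, 9e6))
  gaps <- data.frame(name = "chr1",
                     start = c(1e6, 4.999e6, 7e6, 2e6),
                     end = c(1.01e6, 5.01e6, 7.05e6, 2.001e6))
  r <- gapBridging(segments, gaps, minGap = 2000)
  # the 1-kb gap is filtered; the one straddling a segment end is unbridged
  expect_equal(r$nGaps, 3L)
  expect_equal(r$nBridged, 2L)
  # fully interior planted gaps are all bridged
  withr::local_seed(343)
  g2 <- data.frame(name = "chr1", start = runif(20, 1e5, 4.5e6))
  g2$end <- g2$start + runif(20, 2e3, 2e4)
  expect_equal(gapBridging(segments, g2)$percent, 100)
})

test_that("the published gap tallies reproduce the printed percentages", {
  dt <- omtkFixture("discussion_tallies")
  u <- dt[dt$build == "UMD3.1", ]
  expect_equal(round(100 * u$n_gaps_bridged / u$n_gaps_ge2kb, 1), 96.4)
  expect_gte(100 * u$n_gaps_bridged / u$n_gaps_ge2kb, 96)
  expect_equal(round(100 * u$n_gaps_intersected / u$n_gaps_ge2kb, 1), 27.6)
  expect_equal(round(100 * u$n_disc_intersecting / u$n_discordances, 1), 3.4)
})

test_that("discordance export is ordered, round-trips, and writes links", {
  d <- data.frame(category = c("EC", "IT", "DEL"), chrom = "chr1",
                  seqStart = c(5e5, 1e5, 3e5), seqEnd = c(5e5, 1.2e6, 3.4e5),
                  optStart = c(4e5, 1e5, 2e5), optEnd = c(4e5, 1.1e6, 2.4e5),
                  sizeDiff = c(0, 0, 4e4), subtype = c("none", "inversion",
                                                       "none"),
                  optChrom = "chr1_OM")
  f <- withr::local_tempfile(fileext = ".tsv")
  exportDiscordances(d, f)
  back <- readDiscordances(f)
  expect_equal(nrow(back), 3L)
  expect_true(!is.unsorted(back$seqStart))
  links <- readLines(sub("\\.tsv$", "_links.txt", f))
  expect_equal(length(links), 1L)
  # empty set: header-only file and empty links
  f2 <- withr::local_tempfile(fileext = ".tsv")
  exportDiscordances(d[0, ], f2)
  expect_equal(nrow(readDiscordances(f2)), 0L)
})
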