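test_that("noise-free contigs are placed at exact offsets and strands", {
  tr <- miniTruth(4e6, seed = 261)
  f <- fragments(tr)
  n <- length(f)
  c1 <- FragmentMap("c1", f[10:120], kind = "consensus")
  c2 <- FragmentMap("c2", rev(f[200:330]), kind = "consensus")
  plc <- orderAndOrient(list(c1, c2), list(chr1 = tr))
  expect_equal(nrow(plc), 2L)
  b <- c(0, cumsum(f))
  expect_equal(plc$offset[plc$contigId == "c1"], b[10], tolerance = 1)
  expect_equal(plc$strand[plc$contigId == "c1"], "+")
  expect_equal(plc$offset[plc$contigId == "c2"], b[200], tolerance = 1)
  expect_equal(plc$strand[plc$contigId == "c2"], "-")
  # ordering equals truth ordering
  expect_true(all(diff(plc$offset[order(plc$offset)]) > 0))
})

test_that("stitching inserts exactly n-1 flagged spacers and adds up", {
  c1 <- FragmentMap("a", rep(1e4, 100), kind = "consensus")   # 1 Mb
  c2 <- FragmentMap("b", rep(1e4, 50), kind = "consensus")    # 0.5 Mb
  placed <- data.frame(contigId = c("a", "b"), chrom = "chrT",
                       offset = c(0, 2e6), strand = "+", score = c(10, 9))
  st <- stitchChromosome(placed, list(c1, c2), chrom = "chrT")
  expect_equal(mapSpan(st$map), 1e6 + 5e5 + 5e5)
  expect_equal(sum(gapFlags(st$map)), 1L)
  expect_equal(mapKind(st$map), "chromosome")
  # single contig: no spacer
  st1 <- stitchChromosome(placed[1, ], list(c1), chrom = "chrT")
  expect_equal(sum(gapFlags(st1$map)), 0L)
  # overlapping placements raise by default
  bad <- placed; bad$offset <- c(0, 5e5)
  expect_error(stitchChromosome(bad, list(c1, c2), chrom = "chrT"),
               "overlapping")
})

test_that("identical maps give one full-coverage segment; stitched maps split", {
  tr <- miniTruth(3e6, seed = 271)
  seg <- extractMapSegments(tr, tr)
  expect_equal(seg$stats$nSegments, 1L)
  expect_equal(seg$stats$pctCoverage, 100, tolerance = 0.1)

  f <- fragments(tr); n <- length(f)
  cA <- FragmentMap("A", f[1:floor(n / 2 - 6)], kind = "consensus")
  cB <- FragmentMap("B", f[floor(n / 2 + 6):n], kind = "consensus")
  placed <- orderAndOrient(list(cA, cB), list(chr1 = tr))
  st <- stitchChromosome(placed, list(cA, cB), chrom = "chr1")
  seg2 <- extractMapSegments(st$map, tr, chrom = "chr1")
  expect_gte(seg2$stats$nSegments, 2L)
  # mass bookkeeping: aligned mass below sequence size, coverage consistent
  expect_equal(seg2$stats$pctCoverage,
               100 * sum(seg2$segments$massBp) / mapSpan(tr),
               tolerance = 0.01)
})

test_that("a planted mid-chromosome inversion yields a '-' middle segment", {
  tr <- miniTruth(4e6, seed = 281)
  f <- fragments(tr); n <- length(f)
  i <- round(n * 0.45); j <- round(n * 0.55)   # ~0.4 Mb reversed
  om <- FragmentMap("om", c(f[1:(i - 1)], rev(f[i:j]), f[(j + 1):n]),
                    kind = "chromosome")
  seg <- extractMapSegments(om, tr)
  expect_gte(seg$stats$nSegments, 3L)
  expect_true("-" %in% seg$segments$orientation)
})

test_that("molecule-end pile-ups flag chromosome ends; uniform ends do not", {
  tr <- simulateReference(3e6, seed = 291)
  # linear ends: molecules truncate at the termini
  simL <- simulateRmaps(tr, errorModel(), coverage = 50, seed = 292,
                        ends = "linear")
  asmL <- iterateAssembly(simL$rmaps, tr, cycles = 1)
  big <- asmL$contigs[[which.max(vapply(asmL$contigs, mapSpan, numeric(1)))]]
  fl <- detectChromosomeEnds(big)
  expect_true(any(fl))

  # interior sampling: no pile-up anywhere
  simI <- simulateRmaps(tr, errorModel(), coverage = 50, seed = 293,
                        ends = "interior")
  asmI <- iterateAssembly(simI$rmaps, tr, cycles = 1)
  bigI <- asmI$contigs[[which.max(vapply(asmI$contigs, mapSpan, numeric(1)))]]
  expect_false(any(detectChromosomeEnds(bigI)))

  # too few members can never flag
  few <- big
  few@memberPoses <- big@memberPoses[1:5]
  expect_false(any(detectChromosomeEnds(few)))
})

test_that("terminal optical overhangs are reported as end extensions", {
  tr <- miniTruth(3e6, seed = 301)
  f <- fragments(tr)
  om <- FragmentMap("om", c(300000, 217000, f), kind = "chromosome")
  seg <- extractMapSegments(om, tr)
  ext <- endExtension(om, tr, seg$segments)
  expect_equal(ext$extensionBp[ext$end == "left"], 517000, tolerance = 2e4)
  expect_equal(ext$extensionBp[ext$end == "right"], 0, tolerance = 2e4)
  # identical maps: no extension either side
  ext0 <- endExtension(tr, tr, extractMapSegments(tr, tr)$segments)
  expect_true(all(ext0$extensionBp < 1))
})
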