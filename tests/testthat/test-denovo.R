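test_that("quantization follows the geometric code formula", {
  sch <- quantScheme()
  expect_equal(quantizeMap(c(1000), sch), 0L)
  f <- 1500
  edge <- sch@f0 * (1 + sch@epsilon)^quantizeMap(f, sch)
  expect_equal(quantizeMap(edge * (1 + sch@epsilon)^1.0 * 1.001, sch),
               quantizeMap(edge * 1.001, sch) + 1L)
  m <- FragmentMap("m", c(800, 1500, 9000, 22000))
  expect_identical(quantizeMap(reverseMap(m), sch),
                   rev(quantizeMap(m, sch)))
})

test_that("the confident subgraph of a clean dataset is a simple path", {
  tr <- simulateReference(1e6, seed = 211)
  sim <- simulateRmaps(tr, noiseFreeModel(), coverage = 40, seed = 212)
  g <- buildKmerGraph(sim$rmaps, k = 5, minMult = 5)
  conf <- g$nodes[g$nodes$confident, ]
  expect_gt(nrow(conf), 10)
  # every confident node key appears as a window of the quantized truth
  codes <- quantizeMap(tr, g$scheme)
  wins <- vapply(seq_len(length(codes) - 4), function(s)
    omtk:::.canonical(codes[s:(s + 4)])$key, character(1))
  expect_gte(mean(conf$key %in% wins), 0.97)
  # edges connect truth-consecutive windows for the bulk of the graph
  expect_gt(nrow(g$edges), 10)
})

test_that("a planted exact tandem repeat creates a cycle in the graph", {
  unit <- c(5000, 12000, 7000, 20000, 9000)
  rep10 <- rep(unit, 10)
  maps <- lapply(1:12, function(k) {
    s <- ((k - 1) %% 5) + 1
    FragmentMap(sprintf("m%d", k), rep10[s:(s + 24)])
  })
  g <- buildKmerGraph(RmapSet(maps), k = 5, minMult = 5)
  # repeat of period 5 with k=5: the same canonical 5-mer recurs, and some
  # node must have an edge returning to it within the period
  conf <- g$nodes$key[g$nodes$confident]
  expect_gt(max(g$nodes$mult), 20)
  ed <- g$edges[g$edges$from %in% conf & g$edges$to %in% conf, ]
  reach <- unique(c(ed$from, ed$to))
  expect_lte(length(reach), 5)   # period bounds the distinct k-mers
})

test_that("an over-strict multiplicity threshold leaves no confident nodes", {
  tr <- simulateReference(5e5, seed = 221)
  sim <- simulateRmaps(tr, errorModel(), coverage = 10, seed = 222)
  g <- buildKmerGraph(sim$rmaps, k = 5, minMult = 500)
  expect_equal(sum(g$nodes$confident), 0L)
  expect_equal(length(germinateSeedMaps(g, sim$rmaps)), 0L)
})

test_that("noise-free seed maps are exact sub-maps of the truth", {
  tr <- simulateReference(1e6, seed = 231)
  sim <- simulateRmaps(tr, noiseFreeModel(), coverage = 40, seed = 232)
  g <- buildKmerGraph(sim$rmaps, k = 5, minMult = 5)
  seeds <- germinateSeedMaps(g, sim$rmaps, seedMinDepth = 3)
  expect_gte(length(seeds), 1L)
  for (s in seeds[seq_len(min(4, length(seeds)))]) {
    ag <- mapAgreement(tr, s)
    dev <- ag$qryDev[!is.na(ag$qryDev)]
    expect_gte(mean(dev < 1), 0.95)
  }
})

test_that("orientation canonicalization survives reversing every input", {
  tr <- simulateReference(6e5, seed = 241)
  sim <- simulateRmaps(tr, errorModel(), coverage = 20, seed = 242)
  g1 <- buildKmerGraph(sim$rmaps, k = 4, minMult = 4)
  flipped <- RmapSet(lapply(rmapList(sim$rmaps), reverseMap))
  g2 <- buildKmerGraph(flipped, k = 4, minMult = 4)
  m1 <- g1$nodes$mult; names(m1) <- g1$nodes$key
  m2 <- g2$nodes$mult; names(m2) <- g2$nodes$key
  expect_setequal(names(m1), names(m2))
  expect_identical(m1[sort(names(m1))], m2[sort(names(m1))])
})

test_that("gap-fill assembles only unrecruited molecules", {
  tr <- simulateReference(2e6, seed = 251)
  sim <- simulateRmaps(tr, errorModel(), coverage = 40, seed = 252)
  asm <- iterateAssembly(sim$rmaps, tr, cycles = 1)
  # pretend everything was recruited: nothing left to fill
  all_in <- asm$contigs
  if (length(all_in)) {
    fake <- all_in[[1]]
    fake@members <- rmapIds(sim$rmaps)
    gf0 <- gapfillRound(sim$rmaps, list(fake))
    expect_equal(length(gf0$contigs), 0L)
  }
})
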