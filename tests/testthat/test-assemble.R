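test_that("bins tile with the configured stride and 50% membership rule", {
  poses <- list(list(id = "a", start = 0.9e6, end = 1.3e6, cuts = numeric(0)),
                list(id = "b", start = 0, end = 3e6, cuts = numeric(0)))
  bins <- binAlignments(poses, 1e6, 5e5)
  starts <- vapply(bins, `[[`, numeric(1), "start")
  expect_equal(diff(starts), rep(5e5, length(starts) - 1))
  # footprint [0.9, 1.3] Mb: >= 50% inside bins [0.5,1.5] and [1,2] only
  memberBins <- which(vapply(bins, function(b) 1L %in% b$members, logical(1)))
  expect_equal(starts[memberBins], c(5e5, 1e6))
})

test_that("identical noise-free molecules reproduce their common map exactly", {
  # all fragments above the 2-kb clustering resolution so the identity
  # channel can be exact
  withr::local_seed(141)
  win <- FragmentMap("win", runif(110, 3000, 30000))
  cuts <- cumsum(fragments(win)); cuts <- head(cuts, -1)
  poses <- lapply(1:25, function(k)
    list(id = sprintf("m%02d", k), start = 0, end = mapSpan(win),
         cuts = cuts, mcuts = cuts))
  cc <- buildConsensusFromPoses(poses, minDepth = 20)
  expect_equal(length(cc), 1L)
  expect_equal(fragments(cc[[1]]), fragments(win), tolerance = 1e-9)
  expect_true(all(fragmentDepth(cc[[1]]) == 25))
  expect_true(all(fragmentSpread(cc[[1]]) == 0))
  # below the depth threshold nothing is emitted
  expect_equal(length(buildConsensusFromPoses(poses[1:19], minDepth = 20)),
               0L)
})

test_that("consensus of a consensus's own members reproduces its cut set", {
  tr <- miniTruth(3e6, seed = 151)
  sim <- simulateRmaps(tr, errorModel(), coverage = 40, seed = 152)
  alns <- alignRmapSet(sim$rmaps, tr)
  maps <- rmapList(sim$rmaps); names(maps) <- vapply(maps, mapId, character(1))
  poses <- lapply(names(alns), function(id)
    poseFromAlignment(maps[[id]], alns[[id]], tr))
  cc <- buildConsensusFromPoses(poses, minDepth = 20,
                                anchors = cumsum(fragments(tr)))
  cm <- cc[[which.max(vapply(cc, mapSpan, numeric(1)))]]
  cc2 <- buildConsensusFromPoses(cm@memberPoses, minDepth = 20,
                                 anchors = head(cumsum(fragments(cm)), -1))
  cm2 <- cc2[[which.max(vapply(cc2, mapSpan, numeric(1)))]]
  ag <- mapAgreement(cm, cm2)
  dev <- ag$qryDev[!is.na(ag$qryDev)]
  expect_gte(mean(dev < 1500), 0.97)
})

test_that("default-noise consensus recovers truth cuts with no spurious ones", {
  tr <- simulateReference(5e6, seed = 161)
  sim <- simulateRmaps(tr, errorModel(), coverage = 60, seed = 162)
  asm <- iterateAssembly(sim$rmaps, tr, cycles = 3)
  expect_gte(length(asm$contigs), 1L)
  tcuts <- head(cumsum(fragments(tr)), -1)
  recovered <- rep(FALSE, length(tcuts)); inspan <- rep(FALSE, length(tcuts))
  spurious <- 0
  for (cm in asm$contigs) {
    ag <- mapAgreement(tr, cm)
    inspan <- inspan | ag$refCovered
    recovered <- recovered | (!is.na(ag$refDev) & ag$refDev < 3000)
    qd <- ag$qryDev
    spurious <- spurious + sum(!is.na(qd) & qd > 3000)
  }
  expect_gte(sum(recovered) / sum(inspan), 0.99)
  expect_lte(spurious / (mapSpan(tr) / 1e6), 0.1)
})

test_that("noise-free assembly converges to the exact truth map by cycle 2", {
  tr <- simulateReference(2e6, seed = 171)
  sim <- simulateRmaps(tr, noiseFreeModel(), coverage = 30, seed = 172)
  asm <- iterateAssembly(sim$rmaps, tr, cycles = 2)
  expect_equal(length(asm$contigs), 1L)
  cm <- asm$contigs[[1]]
  ag <- mapAgreement(tr, cm)
  dev <- ag$qryDev[!is.na(ag$qryDev)]
  expect_true(all(dev < 1e-6))
})

test_that("a single cycle equals binning plus consensus composition", {
  tr <- simulateReference(2e6, seed = 181)
  sim <- simulateRmaps(tr, errorModel(), coverage = 30, seed = 182)
  asm1 <- iterateAssembly(sim$rmaps, tr, cycles = 1)
  expect_equal(nrow(asm1$metrics), 1L)
  expect_gte(sum(vapply(asm1$contigs, mapSpan, numeric(1))), 1.5e6)
})

test_that("merging joins constructed overlaps and respects disjointness", {
  tr <- miniTruth(3e6, seed = 191)
  sim <- simulateRmaps(tr, errorModel(), coverage = 40, seed = 192)
  alns <- alignRmapSet(sim$rmaps, tr)
  maps <- rmapList(sim$rmaps); names(maps) <- vapply(maps, mapId, character(1))
  poses <- lapply(names(alns), function(id)
    poseFromAlignment(maps[[id]], alns[[id]], tr))
  starts <- vapply(poses, `[[`, numeric(1), "start")
  left <- poses[starts < 1.8e6]
  right <- poses[starts > 1.2e6]
  anch <- cumsum(fragments(tr))
  ccl <- buildConsensusFromPoses(left, minDepth = 15, anchors = anch,
                                 idPrefix = "L")
  ccr <- buildConsensusFromPoses(right, minDepth = 15, anchors = anch,
                                 idPrefix = "R")
  pair <- c(ccl[1], ccr[1])
  mg <- mergeContigs(pair, minDepth = 15)
  expect_equal(length(mg$contigs), 1L)
  expect_gte(mapSpan(mg$contigs[[1]]), 0.95 *
             (max(vapply(poses, `[[`, numeric(1), "end")) -
              min(vapply(poses, `[[`, numeric(1), "start"))) - 3e5)
  # merging never changes the unique member universe
  expect_setequal(unique(unlist(lapply(mg$contigs, members))),
                  unique(c(members(pair[[1]]), members(pair[[2]]))))

  # disjoint contigs stay apart
  far <- buildConsensusFromPoses(poses[starts > 2.4e6], minDepth = 10,
                                 anchors = anch, idPrefix = "F")
  mg2 <- mergeContigs(c(ccl[1], far[1]), minDepth = 10)
  expect_equal(length(mg2$contigs), 2L)
})

test_that("contig statistics total and average like a contig table", {
  tr <- miniTruth(3e6, seed = 201)
  sim <- simulateRmaps(tr, errorModel(), coverage = 30, seed = 202)
  asm <- iterateAssembly(sim$rmaps, tr, cycles = 1)
  st <- contigStats(asm$contigs)
  tot <- st[st$contig == "Total/Ave.", ]
  per <- st[st$contig != "Total/Ave.", ]
  expect_equal(tot$spanMb, round(sum(per$spanMb), 2))
  expect_equal(tot$nFragments, sum(per$nFragments))
  expect_equal(tot$meanFragKb,
               round(sum(per$spanMb) * 1000 / sum(per$nFragments), 2))
  if (nrow(per) == 1L) expect_equal(tot$spanMb, per$spanMb)
})

test_that("a periodic fragment pattern raises the tandem flag", {
  unit <- c(4000, 9000, 15000)
  flagged <- omtk:::.tandem_flagged(rep(unit, 20))
  expect_true(flagged)
  withr::local_seed(7)
  expect_false(omtk:::.tandem_flagged(runif(60, 2000, 20000)))
})
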