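test_that("simulated references hit the requested length and density", {
  tr <- simulateReference(1e7, seed = 7)
  expect_equal(mapSpan(tr), 1e7)
  expect_gt(nFragments(tr), 1000)
  expect_lt(abs(mean(fragments(tr)) - 8910) / 8910, 0.05)
  expect_true(all(fragments(tr) >= 499))   # 500 bp floor (rounded)
  # determinism
  expect_identical(fragments(simulateReference(1e6, seed = 3)),
                   fragments(simulateReference(1e6, seed = 3)))
  expect_error(simulateReference(5e4), ">=")
})

test_that("the noise-free channel emits exact contiguous sub-maps of truth", {
  tr <- simulateReference(2e6, seed = 5)
  sim <- simulateRmaps(tr, noiseFreeModel(), coverage = 5, seed = 6)
  tcuts <- cumsum(fragments(tr))
  for (k in seq_len(min(10, length(sim$rmaps)))) {
    m <- sim$rmaps[[k]]
    pl <- sim$placements[k, ]
    f <- fragments(m)
    if (pl$strand == "-") f <- rev(f)
    inner <- tcuts[tcuts > pl$start & tcuts < pl$end]
    expect_equal(diff(c(pl$start, inner, pl$end)), f, tolerance = 1e-9)
  }
})

test_that("the simulator's own bookkeeping recovers the digestion rate", {
  tr <- simulateReference(5e6, seed = 11)
  sim <- simulateRmaps(tr, errorModel(), coverage = 60, seed = 12)
  pl <- sim$placements
  phat <- sum(pl$nRetainedSites) / sum(pl$nTrueSites)
  se <- sqrt(0.8 * 0.2 / sum(pl$nTrueSites))
  expect_lt(abs(phat - 0.8), 4 * se + 1e-4)
  # false-cut rate per kb
  fhat <- sum(pl$nFalseCuts) / (sum(pl$end - pl$start) / 1000)
  expect_lt(abs(fhat - 0.005) / 0.005, 0.25)
  # every emitted molecule respects the size filter
  spans <- vapply(rmapList(sim$rmaps), mapSpan, numeric(1))
  expect_true(all(spans >= 3e5))
})

test_that("sizing noise variance grows with true fragment length", {
  tr <- simulateReference(5e6, seed = 21)
  sim <- simulateRmaps(tr, errorModel(falseCutRate = 0, pDigest = 1,
                                      minDetectable = 0),
                       coverage = 30, seed = 22)
  tcuts <- cumsum(fragments(tr))
  resid <- c(); truef <- c()
  for (k in seq_len(length(sim$rmaps))) {
    pl <- sim$placements[k, ]
    f <- fragments(sim$rmaps[[k]])
    if (pl$strand == "-") f <- rev(f)
    inner <- tcuts[tcuts > pl$start & tcuts < pl$end]
    tf <- diff(c(pl$start, inner, pl$end))
    if (length(tf) != length(f)) next
    keep <- 2:(length(f) - 1)          # ends are clamp-affected
    resid <- c(resid, f[keep] - tf[keep]); truef <- c(truef, tf[keep])
  }
  fit <- stats::lm(resid^2 ~ truef)
  slope <- unname(coef(fit)[2])
  expect_lt(abs(slope - errorModel()@sizingVarPerBp) /
            errorModel()@sizingVarPerBp, 0.25)
})

test_that("planted assembly errors follow mass accounting and the ledger", {
  tr <- simulateReference(8e6, seed = 31)
  # one 40-kb gain only
  sp <- plantSpec(nPerCategory = 0)
  sp$DEL <- list(n = 1, size = c(4e4, 4e4))
  pl <- plantAssemblyErrors(tr, spec = sp, seed = 32)
  expect_equal(mapSpan(pl$map) - mapSpan(tr), 4e4, tolerance = 1e-6)
  expect_equal(pl$ledger$category, "DEL")
  expect_equal(pl$ledger$asmEnd - pl$ledger$asmStart, 4e4, tolerance = 1e-6)

  # inversion: the fragment run is reversed in place
  spI <- plantSpec(nPerCategory = 0)
  spI$INV <- list(n = 1, size = c(3e5, 3e5))
  plI <- plantAssemblyErrors(tr, spec = spI, seed = 33)
  expect_equal(mapSpan(plI$map), mapSpan(tr), tolerance = 1e-6)
  led <- plI$ledger
  tcuts <- c(0, cumsum(fragments(tr)))
  i <- which.min(abs(tcuts - led$truthStart)) ; j <- which.min(abs(tcuts - led$truthEnd))
  run <- fragments(tr)[i:(j - 1)]
  ccuts <- c(0, cumsum(fragments(plI$map)))
  i2 <- which.min(abs(ccuts - led$asmStart)); j2 <- which.min(abs(ccuts - led$asmEnd))
  expect_equal(fragments(plI$map)[i2:(j2 - 1)], rev(run), tolerance = 1e-6)
})

test_that("planted events are re-derivable by brute-force map diffing", {
  tr <- simulateReference(2e7, seed = 41)
  pl <- plantAssemblyErrors(tr, spec = plantSpec(nPerCategory = 2), seed = 42)
  led <- pl$ledger
  # EC: corrupted has a cut absent from truth (within 1 bp)
  tcuts <- cumsum(fragments(tr)); ccuts <- cumsum(fragments(pl$map))
  for (k in which(led$category == "EC")) {
    q <- led$asmStart[k]
    expect_gt(min(abs(tcuts - led$truthStart[k])), 1500)
    expect_lt(min(abs(ccuts - q)), 1)
  }
  for (k in which(led$category == "MC")) {
    expect_lt(min(abs(tcuts - led$truthStart[k])), 1)
    expect_gt(min(abs(ccuts - led$asmStart[k])), 2500)
  }
  # mass accounting across all events
  expect_equal(mapSpan(pl$map) - mapSpan(tr), sum(led$sizeDiff),
               tolerance = 1e-6)
  # determinism
  pl2 <- plantAssemblyErrors(tr, spec = plantSpec(nPerCategory = 2), seed = 42)
  expect_identical(fragments(pl$map), fragments(pl2$map))
})

test_that("simulation is deterministic and seed-sensitive", {
  tr <- simulateReference(1e6, seed = 51)
  a <- simulateRmaps(tr, errorModel(), coverage = 10, seed = 52)
  b <- simulateRmaps(tr, errorModel(), coverage = 10, seed = 52)
  expect_identical(lapply(rmapList(a$rmaps), fragments),
                   lapply(rmapList(b$rmaps), fragments))
  c <- simulateRmaps(tr, errorModel(), coverage = 10, seed = 53)
  expect_false(identical(lapply(rmapList(a$rmaps), fragments),
                         lapply(rmapList(c$rmaps), fragments)))
})
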