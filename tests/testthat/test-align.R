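test_that("block scores follow the closed form and are monotone in |x - y|", {
  p <- alignParams()
  expect_equal(scoreBlock(9000, 9000, 0, p), p@matchBonus)
  expect_equal(scoreBlock(9000, 9000, 2, p), p@matchBonus - 2 * p@cutPenalty)
  withr::local_seed(3)
  x <- runif(50, 3000, 30000)
  for (k in 1:50) {
    d <- sort(runif(3, 0, 10000))
    s <- scoreBlock(x[k], x[k] + d, 0, p)
    expect_true(all(diff(s) < 0))
  }
})

test_that("DP fitting score equals exhaustive block-decomposition search", {
  p <- alignParams()
  tr <- miniTruth(2e6, seed = 61)
  sim <- simulateRmaps(tr, errorModel(), coverage = 3, seed = 62)
  tf <- fragments(tr)
  nok <- 0
  withr::local_seed(63)
  for (rep in 1:60) {
    m <- sim$rmaps[[sample(length(sim$rmaps), 1)]]
    qf <- fragments(m)
    if (length(qf) > 12) qf <- qf[1:12]
    j0 <- sample(length(tf) - 15, 1)
    rf <- tf[j0:(j0 + 14)]
    expect_equal(dpFitScore(qf, rf, p), oracleFitScore(qf, rf, p),
                 tolerance = 1e-9)
    nok <- nok + 1
  }
  expect_equal(nok, 60)
})

test_that("noise-free Rmaps align at exactly their truth placements", {
  tr <- miniTruth(3e6, seed = 71)
  sim <- simulateRmaps(tr, noiseFreeModel(), coverage = 5, seed = 72)
  tcuts <- cumsum(fragments(tr))
  hits <- 0
  for (k in seq_len(min(15, length(sim$rmaps)))) {
    a <- alignRmap(sim$rmaps[[k]], tr)
    expect_false(is.null(a))
    pl <- sim$placements[k, ]
    # footprint boundaries are the truth cuts bracketing the placement
    expect_lt(a@refStart, pl$start + 1e-6)
    expect_gt(a@refEnd, pl$end - 1e-6)
    expect_true(all(abs(a@blocks$dev[2:(nrow(a@blocks) - 1)]) < 1e-6))
    hits <- hits + 1
  }
  expect_equal(hits, 15)
})

test_that("orientation symmetry: a reversed query mirrors with equal score", {
  tr <- miniTruth(2e6, seed = 81)
  sim <- simulateRmaps(tr, errorModel(), coverage = 3, seed = 82)
  m <- sim$rmaps[[1]]
  a1 <- alignRmap(m, tr)
  mr <- reverseMap(m)
  a2 <- alignRmap(mr, tr)
  expect_false(is.null(a1)); expect_false(is.null(a2))
  expect_equal(a1@score, a2@score, tolerance = 1e-9)
  expect_equal(a1@refStart, a2@refStart, tolerance = 1e-6)
  expect_false(a1@orientation == a2@orientation)
})

test_that("stored scores equal recomputation from blocks", {
  p <- alignParams()
  tr <- miniTruth(2e6, seed = 91)
  sim <- simulateRmaps(tr, errorModel(), coverage = 5, seed = 92)
  checked <- 0
  for (k in seq_len(min(10, length(sim$rmaps)))) {
    a <- alignRmap(sim$rmaps[[k]], tr, p)
    if (is.null(a)) next
    b <- a@blocks
    n <- nrow(b)
    qend <- c(rep(FALSE, n - 1), TRUE); qstart <- c(TRUE, rep(FALSE, n - 1))
    rend <- b$re == nFragments(tr); rstart <- b$rs == 1
    bl <- b$re - b$rs + 1L; al <- b$qe - b$qs + 1L
    free <- (qstart & b$qryLen < b$refLen & bl <= 2) |
            (qend & b$qryLen < b$refLen & bl <= 2) |
            (rstart & b$refLen < b$qryLen & al <= 2) |
            (rend & b$refLen < b$qryLen & al <= 2)
    s <- p@matchBonus - p@cutPenalty * b$interior -
      ifelse(free, 0, (b$refLen - b$qryLen)^2 /
               (2 * p@sizingVarPerBp * pmax(b$refLen, p@sizingFloor)))
    expect_equal(sum(s), a@score, tolerance = 1e-9)
    checked <- checked + 1
  }
  expect_gte(checked, 8)
})

test_that("self-alignment of a map covers it fully; shuffled maps do not align", {
  tr <- miniTruth(1e6, seed = 101)
  alns <- alignMapPair(tr, tr)
  expect_gte(length(alns), 1L)
  a <- alns[[1]]
  expect_equal(a@refStart, 0)
  expect_equal(a@refEnd, mapSpan(tr))
  expect_equal(a@orientation, "+")

  # null check on the molecule acceptance path: a molecule from one genome
  # must not be accepted against an unrelated reference
  tr2 <- miniTruth(2e6, seed = 104)
  sim <- simulateRmaps(tr2, errorModel(), coverage = 8, seed = 105)
  other <- simulateReference(2e6, seed = 106, id = "other")
  mols <- utils::head(rmapList(sim$rmaps), 40)
  accept <- sum(vapply(mols, function(m)
    !is.null(alignRmap(m, other)), logical(1)))
  expect_lte(accept / length(mols), 0.05)
})

test_that("a central reversed run is recovered in '-' orientation", {
  tr <- miniTruth(2e6, seed = 111)
  f <- fragments(tr)
  n <- length(f)
  i <- round(n * 0.3); j <- round(n * 0.7)
  inv <- FragmentMap("inv", c(f[1:(i - 1)], rev(f[i:j]), f[(j + 1):n]))
  # orientation-restricted extraction sees the reversed body directly
  minus <- alignMapPair(tr, inv, orientations = "-")
  expect_gte(length(minus), 1L)
  expect_gte(max(vapply(minus, slot, numeric(1), "score")), 100)
  # and the segment layer resolves the three-part structure
  seg <- extractMapSegments(inv, tr)
  expect_gte(seg$stats$nSegments, 3L)
  expect_true("-" %in% seg$segments$orientation)
})

test_that("piles and depth profiles follow interval arithmetic", {
  tr <- miniTruth(3e6, seed = 121)
  sim <- simulateRmaps(tr, errorModel(), coverage = 10, seed = 122)
  alns <- alignRmapSet(sim$rmaps, tr)
  pd <- buildPiles(alns, tr)
  expect_equal(length(pd$depth), nFragments(tr))
  w <- fragments(tr)
  meanDepth <- sum(pd$depth * w) / sum(w)
  retained <- sum(vapply(rmapList(sim$rmaps), mapSpan, numeric(1)))
  expect_lt(abs(meanDepth - length(alns) / length(sim$rmaps) *
                retained / mapSpan(tr)) / meanDepth, 0.2)
  expect_identical(buildPiles(list(), tr)$depth, integer(nFragments(tr)))
})

test_that("build evaluation separates the truth build from a corrupted one", {
  tr <- miniTruth(5e6, seed = 131)
  sim <- simulateRmaps(tr, errorModel(), coverage = 12, seed = 132)
  evT <- evaluateBuild(sim$rmaps, tr)
  expect_gte(evT$fractionAligned, 0.9)
  sp <- plantSpec(nPerCategory = 0)
  sp$DEL <- list(n = 2, size = c(3e4, 6e4))
  sp$INS <- list(n = 1, size = c(3e4, 6e4))
  bad <- plantAssemblyErrors(tr, spec = sp, seed = 133, structGuard = 4e5)
  evB <- evaluateBuild(sim$rmaps, bad$map)
  expect_lt(evB$meanDepth, evT$meanDepth)
  # no acceptance at an impossible threshold
  ev0 <- evaluateBuild(RmapSet(rmapList(sim$rmaps)[1:5]), tr,
                       alignParams(minScore = Inf))
  expect_equal(ev0$fractionAligned, 0)
})
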