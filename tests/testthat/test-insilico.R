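test_that("digestion reproduces a hand-scanned site layout", {
  seq <- paste0(strrep("A", 10), "GGATCC", strrep("A", 34),
                "GGATCC", strrep("T", 44))
  d <- digestSequence(seq)
  expect_equal(d$cutSites, c(11, 51))
  expect_equal(fragments(d$map), c(11, 40, 49))
  expect_equal(mapSpan(d$map), nchar(seq))
  expect_equal(mapKind(d$map), "insilico")

  expect_equal(nFragments(digestSequence(strrep("ACT", 400))$map), 1L)
  expect_error(digestSequence(""), "empty")
})

test_that("sites overlapping ambiguity codes are not called", {
  seq <- paste0("GGATCC", strrep("N", 20), "GGATCC", strrep("A", 10))
  d <- digestSequence(seq)
  # cleavage after position 0 is outside (0, len); only interior cleavages
  expect_equal(d$cutSites, c(1, 27))
  seqN <- paste0(strrep("A", 10), "GGNTCC", strrep("A", 20))
  expect_equal(length(digestSequence(seqN)$cutSites), 0L)
})

test_that("digestion matches a string-scan oracle on random sequences", {
  withr::local_seed(5)
  for (rep in 1:5) {
    base <- sample(c("A", "C", "T"), 5000, replace = TRUE)
    pos <- sort(sample(seq(10, 4950, by = 25), 12))
    for (p0 in pos) base[p0:(p0 + 5)] <- c("G", "G", "A", "T", "C", "C")
    s <- paste(base, collapse = "")
    # independent scan
    starts <- gregexpr("GGATCC", s, fixed = TRUE)[[1]]
    cleav <- as.numeric(starts) - 1 + 1
    cleav <- cleav[cleav > 0 & cleav < nchar(s)]
    d <- digestSequence(s)
    expect_equal(d$cutSites, cleav)
    expect_equal(sum(fragments(d$map)), nchar(s))
  }
})

test_that("reverse-complement symmetry holds for the palindromic site", {
  withr::local_seed(9)
  truth <- simulateReference(2e5, seed = 33)
  s <- simulateSequence(truth, seed = 34)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  f1 <- fragments(digestSequence(s)$map)
  f2 <- fragments(digestSequence(rc)$map)
  expect_equal(length(f1), length(f2))
  # interior fragments are inter-cut distances and reverse exactly; the
  # two end pieces shift by the 4-nt stagger of the G^GATCC cleavage
  expect_equal(f2[2:(length(f2) - 1)], rev(f1)[2:(length(f1) - 1)])
  expect_lte(max(abs(sort(f1) - sort(f2))), 4)
})

test_that("a simulated truth map is faithfully realized as sequence", {
  truth <- simulateReference(3e5, seed = 21)
  s <- simulateSequence(truth, seed = 22)
  d <- digestSequence(s)
  expect_equal(fragments(d$map), fragments(truth))
})

test_that("N-gap discovery is exact on planted runs", {
  g1 <- findSequenceGaps(paste0("ACGT", strrep("N", 2500), "ACGT"))
  expect_equal(nrow(g1), 1L)
  expect_equal(g1$length, 2500)
  expect_equal(g1$start, 4)
  g2 <- findSequenceGaps(paste0("ACGT", strrep("N", 1999), "ACGT"))
  expect_equal(nrow(g2), 0L)

  withr::local_seed(13)
  lens <- sample(500:5000, 10)
  parts <- character(0)
  for (l in lens) parts <- c(parts, strrep("A", 3000), strrep("N", l))
  s <- paste0(paste(parts, collapse = ""), strrep("C", 3000))
  got <- findSequenceGaps(s, minLen = 2000)
  expect_equal(got$length, lens[lens >= 2000])
})

test_that("multi-record digestion delegates per record and rejects dup names", {
  t1 <- simulateReference(1.5e5, seed = 41, id = "chrA")
  t2 <- simulateReference(1.2e5, seed = 42, id = "chrB")
  ss <- Biostrings::DNAStringSet(c(chrA = simulateSequence(t1, seed = 43),
                                   chrB = simulateSequence(t2, seed = 44)))
  res <- digestGenome(ss)
  expect_named(res, c("chrA", "chrB"))
  expect_equal(fragments(res$chrA$map),
               fragments(digestSequence(as.character(ss[[1]]), id = "chrA")$map))
  expect_equal(mapSpan(res$chrB$map), 1.2e5)
  ssd <- Biostrings::DNAStringSet(c(chrA = "ACGT", chrA = "ACGT"))
  expect_error(digestGenome(ssd), "duplicate")
})
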