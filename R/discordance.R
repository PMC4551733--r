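# Classification of sequence-vs-optical-map discordances into six
# categories, IT detection from split alignments, gap intersection and
# gap-bridging analyses, and data export.
#
# Direction convention (assembly judged against the optical map): EC = cut
# present in the sequence but unsupported by the map; MC = cut in the map
# absent from the sequence; DEL = extraneous sequence in the assembly
# (signed size difference sequence - optical > 0); INS = missing sequence
# (< 0); COMPLEX = compound/misassembly; IT = large inverted or
# translocated block.

#' Default discordance-calling thresholds
#'
#' @param indelMin minimum indel size bp (floor of the max(10 kb, 4 sigma)
#'   rule).
#' @param indelSigma sizing-SD multiplier for the indel threshold.
#' @param complexWindow window bp for clustering compound events.
#' @param complexMinEvents events within a window that make a COMPLEX.
#' @param mergeRadius events closer than this merge (bp).
#' @param minGapMass unaligned regions with less mass than this on both
#'   sides are treated as clean joins.
#' @param minResolvableFrag cuts whose flanking fragment falls below this
#'   length (bp) are below the effective optical resolution (sub-detectable
#'   fragments merge on the surface, and consensus cut clustering cannot
#'   separate cuts closer than its radius) and are never called EC/MC.
#' @export
discordThresholds <- function(indelMin = 1e4, indelSigma = 4,
                              complexWindow = 1e5, complexMinEvents = 3,
                              mergeRadius = 5e3, minGapMass = 3e3,
                              minResolvableFrag = 2200) {
  list(indelMin = indelMin, indelSigma = indelSigma,
       complexWindow = complexWindow, complexMinEvents = complexMinEvents,
       mergeRadius = mergeRadius, minGapMass = minGapMass,
       minResolvableFrag = minResolvableFrag)
}


# Structural blocks (inverted or displaced runs) hide inside forward
# alignments: with a per-block match bonus, a garbage-bridged chain over
# such a run is close to score-neutral, so extraction alone cannot be
# relied on to split there.  Regions the forward pass explains only at
# garbage score density are re-aligned in isolation, in both
# orientations, and the winning interpretation is kept.
.resolveStructure <- function(buildMap, chromMap, p, minItSize = 1e5) {
  plus <- alignMapPair(buildMap, chromMap, p, orientations = "+")
  nR <- nFragments(buildMap)
  Rb <- c(0, cumsum(fragments(buildMap)))
  dp <- rep(0, nR)
  for (a in plus) {
    b <- a@blocks
    sc <- p@matchBonus - p@cutPenalty * b$interior -
      b$dev^2 / (2 * p@sizingVarPerBp * pmax(b$refLen, p@sizingFloor))
    for (k in seq_len(nrow(b)))
      dp[b$rs[k]:b$re[k]] <- sc[k] / (b$re[k] - b$rs[k] + 1L)
  }
  low <- stats::runmed(dp, 9) < 1.5
  r <- rle(low)
  iend <- cumsum(r$lengths); istart <- iend - r$lengths + 1L
  runs <- cbind(istart[r$values], iend[r$values])
  if (nrow(runs) > 1L) {        # one event can dip in several pieces
    merged <- list(runs[1, ])
    for (kk in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      if (runs[kk, 1] - last[2] <= 12L)
        merged[[length(merged)]] <- c(last[1], runs[kk, 2])
      else merged[[length(merged) + 1L]] <- runs[kk, ]
    }
    runs <- do.call(rbind, merged)
  }
  extras <- list()
  for (kk in seq_len(nrow(runs))) {
    i0 <- runs[kk, 1]; i1 <- runs[kk, 2]
    if (Rb[i1 + 1L] - Rb[i0] < minItSize) next
    maskA2 <- rep(TRUE, nR)
    maskA2[i0:i1] <- FALSE
    cand <- c(alignMapPair(buildMap, chromMap, p, orientations = "+",
                           maskA = maskA2, maxAlignments = 2L),
              alignMapPair(buildMap, chromMap, p, orientations = "-",
                           maskA = maskA2, maxAlignments = 2L))
    cand <- Filter(function(a)
      a@refEnd - a@refStart >= 0.5 * minItSize, cand)
    if (!length(cand)) next
    best <- which.max(vapply(cand, slot, numeric(1), "score"))
    ori <- cand[[best]]@orientation
    extras <- c(extras, Filter(function(a) a@orientation == ori, cand))
  }
  list(plus = plus, extras = extras)
}

.empty_disc <- function() {
  data.frame(category = character(0), chrom = character(0),
             seqStart = numeric(0), seqEnd = numeric(0),
             optStart = numeric(0), optEnd = numeric(0),
             sizeDiff = numeric(0), subtype = character(0))
}

#' Call discordances between a build chromosome and its optical map
#'
#' Works from the chain of colinear local alignments between the build's in
#' silico map (reference side) and the optical chromosome map.  Within
#' aligned blocks, unmatched interior sequence cuts become ECs and unmatched
#' optical cuts become MCs; matched blocks with a size anomaly above
#' \code{max(indelMin, indelSigma * sigma)} become DEL/INS.  Unaligned
#' regions between colinear anchors are classified by their mass difference
#' and cut content (clean DEL/INS, or COMPLEX).  Finally, events closer
#' than \code{mergeRadius} merge, and any run of at least
#' \code{complexMinEvents} events inside \code{complexWindow} collapses to
#' one COMPLEX spanning it.
#'
#' @param chromMap optical chromosome map.
#' @param buildMap build chromosome in silico map.
#' @param p AlignmentParams.
#' @param thresholds see \code{\link{discordThresholds}}.
#' @param chrom chromosome name for the output.
#' @param junctions optional per-junction placement deltas from
#'   \code{\link{stitchChromosome}}: at a contig junction, the flanking
#'   placements' overlap (negative delta) or gap (positive delta) on the
#'   build measures the local size difference directly and overrides the
#'   mass-based gap classification.
#' @param optDepth optional per-fragment consensus depth of
#'   \code{chromMap}: interior regions where molecule recruitment drops
#'   well below the local depth (a structural disagreement suppresses
#'   molecule alignment without leaving a sizing signature) are flagged as
#'   COMPLEX.
#' @return data.frame(category, chrom, seqStart, seqEnd, optStart, optEnd,
#'   sizeDiff, subtype).
#' @export
callDiscordances <- function(chromMap, buildMap, p = alignParams(),
                             thresholds = discordThresholds(),
                             chrom = mapId(buildMap), optDepth = NULL,
                             junctions = NULL) {
  th <- thresholds
  alns <- alignMapPair(buildMap, chromMap, p)
  if (!length(alns)) return(.empty_disc())
  # colinear '+' backbone ordered along the sequence
  plus <- Filter(function(a) a@orientation == "+", alns)
  if (!length(plus)) return(.empty_disc())
  ord <- order(vapply(plus, slot, numeric(1), "refStart"))
  plus <- plus[ord]
  Rb <- c(0, cumsum(fragments(buildMap)))
  nOpt <- nFragments(chromMap)
  optB <- c(0, cumsum(fragments(chromMap)))
  optFlags <- gapFlags(chromMap)

  ev <- list()
  add <- function(category, s0, s1, o0, o1, sizeDiff = 0) {
    ev[[length(ev) + 1L]] <<- data.frame(category = category, chrom = chrom,
      seqStart = s0, seqEnd = s1, optStart = o0, optEnd = o1,
      sizeDiff = sizeDiff, subtype = "none")
  }
  opt_pos <- function(a, qIdxBoundary) {
    # boundary index in aligned orientation -> bp in chromMap coordinates
    if (a@orientation == "+") optB[qIdxBoundary + 1L]
    else optB[nOpt - qIdxBoundary + 1L]
  }

  for (a in plus) {
    b <- a@blocks
    for (k in seq_len(nrow(b))) {
      x <- b$refLen[k]; y <- b$qryLen[k]
      nEC <- b$re[k] - b$rs[k]; nMC <- b$qe[k] - b$qs[k]
      rf <- fragments(buildMap)
      qryf <- fragments(chromMap)
      if (nEC > 0) {
        for (r in b$rs[k]:(b$re[k] - 1L)) {
          # below the optical resolution limit: not a callable discordance
          if (min(rf[r], rf[r + 1L]) < th$minResolvableFrag) next
          add("EC", Rb[r + 1L], Rb[r + 1L],
              opt_pos(a, b$qs[k] - 1L), opt_pos(a, b$qe[k]))
        }
      }
      if (nMC > 0) {
        for (qq in b$qs[k]:(b$qe[k] - 1L)) {
          oi <- if (a@orientation == "+") qq else nOpt - qq
          if (oi >= 1L && oi < nOpt &&
              min(qryf[oi], qryf[oi + 1L]) < th$minResolvableFrag) next
          # interpolate the optical cut into sequence coordinates
          frac <- (optB[min(qq, nOpt) + 1L] - optB[b$qs[k]]) /
                  max(y, 1)
          spos <- Rb[b$rs[k]] + frac * x
          add("MC", spos, spos, opt_pos(a, qq), opt_pos(a, qq))
        }
      }
      # the optical side is a consensus built at depth >= 20, so its
      # sizing error is the single-molecule error shrunk accordingly
      sig <- sqrt(p@sizingVarPerBp * max(x, p@sizingFloor) / 20)
      if (abs(x - y) >= max(th$indelMin, th$indelSigma * sig) &&
          nEC + nMC <= 1L) {
        add(if (x > y) "DEL" else "INS", Rb[b$rs[k]], Rb[b$re[k] + 1L],
            opt_pos(a, b$qs[k] - 1L), opt_pos(a, b$qe[k]), x - y)
      }
    }
    # indels the DP bridged by smearing the size difference over several
    # blocks: windowed cumulative-deviation scan (terminal blocks are
    # shear/boundary-affected and excluded)
    nb <- nrow(b)
    if (nb >= 4L) {
      varb <- p@sizingVarPerBp * pmax(b$refLen, p@sizingFloor) / 20
      cands <- list()
      for (i in 2:(nb - 1L)) {
        S <- 0; V <- 0
        for (j in i:min(nb - 1L, i + 11L)) {
          S <- S + b$dev[j]; V <- V + varb[j]
          thr <- max(th$indelMin, th$indelSigma * sqrt(V))
          if (abs(S) >= thr)
            cands[[length(cands) + 1L]] <- c(i, j, S, abs(S) / thr)
        }
      }
      if (length(cands)) {
        cm <- do.call(rbind, cands)
        cm <- cm[order(-cm[, 4]), , drop = FALSE]
        taken <- rep(FALSE, nb)
        for (r in seq_len(nrow(cm))) {
          i <- cm[r, 1]; j <- cm[r, 2]
          if (any(taken[i:j])) next
          taken[i:j] <- TRUE
          S <- cm[r, 3]
          add(if (S > 0) "DEL" else "INS",
              Rb[b$rs[i]], Rb[b$re[j] + 1L],
              opt_pos(a, b$qs[i] - 1L), opt_pos(a, b$qe[j]), S)
        }
      }
    }
  }

  # unaligned regions between consecutive colinear anchors
  if (length(plus) > 1L) {
    for (k in seq_len(length(plus) - 1L)) {
      a1 <- plus[[k]]; a2 <- plus[[k + 1L]]
      s0 <- a1@refEnd; s1 <- a2@refStart
      b1 <- a1@blocks; b2 <- a2@blocks
      q1 <- if (a1@orientation == "+") b1$qe[nrow(b1)] else NA
      q2 <- if (a2@orientation == "+") b2$qs[1] - 1L else NA
      if (is.na(q1) || is.na(q2)) next
      o0 <- optB[q1 + 1L]; o1 <- optB[q2 + 1L]
      X <- s1 - s0; Y <- o1 - o0
      if (X < -th$mergeRadius || Y < -th$mergeRadius) next
      X <- max(X, 0); Y <- max(Y, 0)
      # ignore clean abutments and spacer-only gaps
      spacerMass <- if (q2 >= q1 + 1L)
        sum(fragments(chromMap)[(q1 + 1L):q2][optFlags[(q1 + 1L):q2]]) else 0
      Yeff <- Y - spacerMass
      if (X <= th$minGapMass && Yeff <= th$minGapMass) next
      nr <- sum(Rb > s0 + 1 & Rb < s1 - 1)
      nspacer <- if (q2 >= q1 + 1L) sum(optFlags[(q1 + 1L):q2]) else 0L
      nq <- max(0, sum(optB > o0 + 1 & optB < o1 - 1) - 2L * nspacer)
      d <- X - Yeff
      # the net mass difference across a gap is a consensus-vs-sequence
      # comparison: its error is the (depth-averaged) consensus sizing
      # error over the gap, not single-molecule noise
      sigG <- sqrt(p@sizingVarPerBp * max(max(X, Yeff), p@sizingFloor) / 20)
      thrG <- max(th$indelMin, th$indelSigma * sigG)
      if (!is.null(junctions) && nrow(junctions)) {
        jin <- junctions$placementDelta[junctions$optPos > o0 &
                                        junctions$optPos < o1]
        if (length(jin) == 1L) {
          d <- jin
          # the flanking contigs' unaligned tails tell the two indel
          # directions apart: extraneous build sequence (DEL) leaves the
          # tails made of ordinary build material, which re-aligns near
          # the junction; missing sequence (INS) leaves tail content the
          # build simply does not have
          sidx <- intersect(which(optFlags), (q1 + 1L):q2)
          if (length(sidx) == 1L) {
            tailL <- if (sidx - 1L >= q1 + 1L)
              fragments(chromMap)[(q1 + 1L):(sidx - 1L)] else numeric(0)
            tailR <- if (q2 >= sidx + 1L)
              fragments(chromMap)[(sidx + 1L):q2] else numeric(0)
            leftSide <- length(tailL) >= length(tailR)
            tail <- if (leftSide) tailL else tailR
            if (length(tail) >= 8L) {
              tm <- FragmentMap("tail", tail)
              pt <- alignParams(minScore = 12, minAlignedFragments = 6,
                                sizingVarPerBp = p@sizingVarPerBp,
                                sizingFloor = p@sizingFloor)
              ta <- alignMapPair(buildMap, tm, pt, maxAlignments = 1L)
              if (length(ta) && ta[[1]]@orientation == "+") {
                off <- .pair_offset(ta[[1]], buildMap, tm)
                # signed displacement of the tail from placement
                # contiguity: + extraneous build sequence, - missing
                disp <- if (leftSide) off - s0 else s1 - (off + sum(tail))
                if (abs(disp) <= 4e5) d <- disp
              } else {
                d <- -max(abs(jin), th$indelMin)
              }
            }
          }
        }
      }
      if (d >= thrG) {
        add("DEL", s0, s1, o0, o1, d)
      } else if (-d >= thrG) {
        add("INS", s0, s1, o0, o1, d)
      } else if (nr + nq >= th$complexMinEvents &&
                 max(X, Yeff) >= th$indelMin) {
        add("COMPLEX", s0, s1, o0, o1, d)
      } else if (min(X, Yeff) >= 2 * th$indelMin) {
        # unalignable interior region flanked by aligned anchors
        add("COMPLEX", s0, s1, o0, o1, d)
      }
    }
  }

  # molecule-recruitment dips: interior runs of fragments whose depth is
  # well below the contig-level background, recovering on both sides
  # (contig-edge ramps lack interior recovery and are excluded)
  if (!is.null(optDepth) && length(optDepth) == nOpt) {
    ctgid <- cumsum(optFlags) + 1L
    ctgid[optFlags] <- NA
    for (cg in unique(ctgid[!is.na(ctgid)])) {
      idxs <- which(!is.na(ctgid) & ctgid == cg)
      dd <- optDepth[idxs]
      if (length(dd) < 30L || all(is.na(dd))) next
      bg <- median(dd, na.rm = TRUE)
      low <- !is.na(dd) & dd < 0.65 * bg
      r <- rle(low)
      iend <- cumsum(r$lengths); istart <- iend - r$lengths + 1L
      for (kk in which(r$values)) {
        i0 <- idxs[istart[kk]]; i1 <- idxs[iend[kk]]
        if (optB[i1 + 1L] - optB[i0] < 2e4) next
        leftHi <- idxs[idxs < i0 & !is.na(optDepth[idxs]) &
                       optDepth[idxs] >= 0.85 * bg]
        rightHi <- idxs[idxs > i1 & !is.na(optDepth[idxs]) &
                        optDepth[idxs] >= 0.85 * bg]
        if (length(leftHi) < 5L || length(rightHi) < 5L) next
        # map the optical interval to sequence coordinates via the backbone
        o0 <- optB[i0]; o1 <- optB[i1 + 1L]
        spos <- NA_real_; epos <- NA_real_
        for (a in plus) {
          bl <- a@blocks
          qlo <- bl$qs[1]; qhi <- bl$qe[nrow(bl)]
          if (i0 >= qlo && i1 <= qhi) {
            kb0 <- which(bl$qs <= i0 & bl$qe >= i0)[1]
            kb1 <- which(bl$qs <= i1 & bl$qe >= i1)[1]
            if (!is.na(kb0)) spos <- Rb[bl$rs[kb0]]
            if (!is.na(kb1)) epos <- Rb[bl$re[kb1] + 1L]
            break
          }
        }
        if (is.na(spos) || is.na(epos) || epos <= spos) next
        ev[[length(ev) + 1L]] <- data.frame(category = "COMPLEX",
          chrom = chrom, seqStart = spos, seqEnd = epos,
          optStart = o0, optEnd = o1, sizeDiff = 0, subtype = "depth_dip")
      }
    }
  }

  if (!length(ev)) return(.empty_disc())
  disc <- do.call(rbind, ev)
  disc <- disc[order(disc$seqStart), , drop = FALSE]

  # merge same-category point events closer than mergeRadius
  keep <- rep(TRUE, nrow(disc))
  for (k in seq_len(nrow(disc))[-1]) {
    if (disc$category[k] %in% c("EC", "MC") && keep[k]) {
      prev <- max(which(keep[1:(k - 1)] &
                        disc$category[1:(k - 1)] == disc$category[k]),
                  -Inf)
      if (is.finite(prev) &&
          disc$seqStart[k] - disc$seqEnd[prev] < th$mergeRadius)
        keep[k] <- FALSE
    }
  }
  disc <- disc[keep, , drop = FALSE]

  # an indel (or an unalignable region) absorbs point events inside its
  # own interval; they are facets of the same discordance
  span <- disc$category %in% c("DEL", "INS", "COMPLEX")
  if (any(span)) {
    pt <- which(!span)
    drop <- logical(nrow(disc))
    for (k in pt) {
      drop[k] <- any(span &
        disc$seqStart - th$mergeRadius <= disc$seqStart[k] &
        disc$seqEnd + th$mergeRadius >= disc$seqEnd[k])
    }
    disc <- disc[!drop, , drop = FALSE]
  }

  # compound windows: >= complexMinEvents point events chained within the
  # window -- or a chain mixing extra and missing cuts, which no single
  # site change produces -- collapse to one COMPLEX; indel calls never
  # re-classify
  n <- nrow(disc)
  if (n >= th$complexMinEvents) {
    ispt <- disc$category %in% c("EC", "MC")
    gapsc <- c(Inf, diff(disc$seqStart))
    cl <- cumsum(gapsc > th$complexWindow / 2 | !ispt |
                 c(FALSE, !ispt[-n]))
    out <- list()
    for (g in unique(cl)) {
      gi <- which(cl == g)
      mixed <- length(gi) >= 2L && all(ispt[gi]) &&
        all(c("EC", "MC") %in% disc$category[gi])
      if ((length(gi) >= th$complexMinEvents || mixed) && all(ispt[gi])) {
        out[[length(out) + 1L]] <- data.frame(category = "COMPLEX",
          chrom = chrom, seqStart = min(disc$seqStart[gi]),
          seqEnd = max(disc$seqEnd[gi]),
          optStart = min(disc$optStart[gi]),
          optEnd = max(disc$optEnd[gi]),
          sizeDiff = sum(disc$sizeDiff[gi]), subtype = "none")
      } else out[[length(out) + 1L]] <- disc[gi, ]
    }
    disc <- do.call(rbind, out)
  }
  rownames(disc) <- NULL
  disc[order(disc$chrom, disc$seqStart, disc$category), , drop = FALSE]
}

#' Call inverted/translocated sequence blocks (ITs)
#'
#' Aligns every optical chromosome map against every build chromosome; an
#' aligned block of at least \code{minItSize} that is non-colinear with the
#' backbone of its optical map -- on another chromosome, out of order, or in
#' '-' orientation -- is called an IT with a subtype (inversion,
#' translocation, or both).  Colinear blocks are never called.
#'
#' @param chromMaps named list of optical chromosome maps.
#' @param buildMaps named list of build chromosome in silico maps.
#' @param minItSize minimum block size bp (default 100 kb).
#' @param p AlignmentParams.
#' @return data.frame(category = "IT", chrom, seqStart, seqEnd, optChrom,
#'   optStart, optEnd, sizeDiff, subtype).
#' @export
callITs <- function(chromMaps, buildMaps, minItSize = 1e5,
                    p = alignParams()) {
  recs <- list()
  for (cb in names(buildMaps)) for (cc in names(chromMaps)) {
    rs <- .resolveStructure(buildMaps[[cb]], chromMaps[[cc]], p, minItSize)
    if (length(rs$extras)) {
      maskA <- rep(FALSE, nFragments(buildMaps[[cb]]))
      for (m in rs$extras)
        maskA[m@blocks$rs[1]:m@blocks$re[nrow(m@blocks)]] <- TRUE
      alns <- c(alignMapPair(buildMaps[[cb]], chromMaps[[cc]], p,
                             orientations = "+", maskA = maskA),
                rs$extras)
    } else {
      alns <- rs$plus
    }
    nOpt <- nFragments(chromMaps[[cc]])
    optB <- c(0, cumsum(fragments(chromMaps[[cc]])))
    for (a in alns) {
      b <- a@blocks
      qlo <- b$qs[1]; qhi <- b$qe[nrow(b)]
      if (a@orientation == "-") { t <- qlo; qlo <- nOpt + 1L - qhi
                                  qhi <- nOpt + 1L - t }
      recs[[length(recs) + 1L]] <- data.frame(build = cb, opt = cc,
        seqStart = a@refStart, seqEnd = a@refEnd,
        optStart = optB[qlo], optEnd = optB[qhi + 1L],
        orientation = a@orientation, mass = a@refEnd - a@refStart)
    }
  }
  if (!length(recs)) return(cbind(.empty_disc(), optChrom = character(0)))
  recs <- do.call(rbind, recs)
  out <- list()
  for (cc in unique(recs$opt)) {
    rc <- recs[recs$opt == cc, , drop = FALSE]
    mass_by_build <- tapply(rc$mass, rc$build, sum)
    main <- names(mass_by_build)[which.max(mass_by_build)]
    bb <- rc[rc$build == main & rc$orientation == "+", , drop = FALSE]
    bb <- bb[order(-bb$mass), , drop = FALSE]
    backbone <- list()
    for (k in seq_len(nrow(bb))) {
      cand <- bb[k, ]
      ok <- all(vapply(backbone, function(x)
        sign(cand$seqStart - x$seqStart) ==
          sign(cand$optStart - x$optStart), logical(1)))
      if (ok) backbone[[length(backbone) + 1L]] <- cand
    }
    bbdf <- do.call(rbind, backbone)
    isBackbone <- rc$build == main & rc$orientation == "+" &
      paste(rc$seqStart, rc$optStart) %in%
      paste(bbdf$seqStart, bbdf$optStart)
    extras <- rc[!isBackbone & rc$mass >= minItSize, , drop = FALSE]
    if (!nrow(extras)) next
    # expected sequence position for an optical position, from the backbone
    expect_seq <- function(optPos) {
      if (is.null(bbdf) || !nrow(bbdf)) return(NA_real_)
      k <- which.min(abs((bbdf$optStart + bbdf$optEnd) / 2 - optPos))
      bbdf$seqStart[k] + (optPos - bbdf$optStart[k])
    }
    for (k in seq_len(nrow(extras))) {
      e <- extras[k, ]
      if (e$build != main) { sub <- "translocation" }
      else {
        expd <- expect_seq((e$optStart + e$optEnd) / 2)
        inPlace <- !is.na(expd) &&
          abs(expd - (e$seqStart + e$seqEnd) / 2) <
            max(2 * (e$seqEnd - e$seqStart), 5e5)
        if (e$orientation == "-") sub <- if (inPlace) "inversion" else "both"
        else sub <- "translocation"
      }
      out[[length(out) + 1L]] <- data.frame(category = "IT", chrom = e$build,
        seqStart = e$seqStart, seqEnd = e$seqEnd, optChrom = e$opt,
        optStart = e$optStart, optEnd = e$optEnd,
        sizeDiff = 0, subtype = sub)
    }
  }
  if (!length(out)) return(cbind(.empty_disc()[, 1:2],
                                 data.frame(seqStart = numeric(0),
                                            seqEnd = numeric(0),
                                            optChrom = character(0),
                                            optStart = numeric(0),
                                            optEnd = numeric(0),
                                            sizeDiff = numeric(0),
                                            subtype = character(0))))
  res <- do.call(rbind, out)
  # pieces of one displaced/reversed run re-align separately; adjacent
  # same-subtype calls are one event
  res <- res[order(res$chrom, res$subtype, res$seqStart), , drop = FALSE]
  if (nrow(res) > 1L) {
    merged <- list(res[1, ])
    for (k in 2:nrow(res)) {
      last <- merged[[length(merged)]]
      if (res$chrom[k] == last$chrom && res$subtype[k] == last$subtype &&
          res$optChrom[k] == last$optChrom &&
          res$seqStart[k] - last$seqEnd < 2.5e5) {
        last$seqEnd <- max(last$seqEnd, res$seqEnd[k])
        last$optStart <- min(last$optStart, res$optStart[k])
        last$optEnd <- max(last$optEnd, res$optEnd[k])
        merged[[length(merged)]] <- last
      } else merged[[length(merged) + 1L]] <- res[k, ]
    }
    res <- do.call(rbind, merged)
  }
  # a reverse-orientation call whose optical footprint is already claimed
  # by a stronger forward alignment is a shadow of that alignment
  keep <- rep(TRUE, nrow(res))
  for (k in seq_len(nrow(res))) {
    if (!res$subtype[k] %in% c("inversion", "both")) next
    w <- res$optEnd[k] - res$optStart[k]
    rc2 <- recs[recs$opt == res$optChrom[k] & recs$orientation == "+" &
                recs$mass >= w, , drop = FALSE]
    if (!nrow(rc2)) next
    ov <- pmin(rc2$optEnd, res$optEnd[k]) - pmax(rc2$optStart, res$optStart[k])
    if (any(ov > 0.5 * w)) keep[k] <- FALSE
  }
  res[keep, , drop = FALSE]
}

#' Intersect discordances with sequence gaps
#'
#' Counts, in both directions, half-open interval overlaps between
#' discordance sequence intervals and N-gap intervals; percentages are
#' reported at one decimal.
#'
#' @param disc discordance data.frame (seqStart, seqEnd, chrom, category).
#' @param gaps gap data.frame (name, start, end) -- 0-based half-open, the
#'   \code{name} column matching \code{disc$chrom}.
#' @return list(nDiscordances, nGaps, nDiscIntersecting, nGapsIntersected,
#'   pctDisc, pctGaps, byCategory).
#' @export
intersectGaps <- function(disc, gaps) {
  nd <- nrow(disc); ng <- nrow(gaps)
  if (nd == 0 || ng == 0)
    return(list(nDiscordances = nd, nGaps = ng, nDiscIntersecting = 0L,
                nGapsIntersected = 0L, pctDisc = 0, pctGaps = 0,
                byCategory = table(character(0))))
  dIR <- IRanges::IRanges(start = floor(disc$seqStart) + 1L,
                          end = pmax(floor(disc$seqEnd), floor(disc$seqStart) + 1L))
  gIR <- IRanges::IRanges(start = floor(gaps$start) + 1L,
                          end = floor(gaps$end))
  hits <- IRanges::findOverlaps(dIR, gIR)
  sameChrom <- disc$chrom[S4Vectors::queryHits(hits)] ==
               gaps$name[S4Vectors::subjectHits(hits)]
  qh <- unique(S4Vectors::queryHits(hits)[sameChrom])
  sh <- unique(S4Vectors::subjectHits(hits)[sameChrom])
  list(nDiscordances = nd, nGaps = ng,
       nDiscIntersecting = length(qh), nGapsIntersected = length(sh),
       pctDisc = round(100 * length(qh) / nd, 1),
       pctGaps = round(100 * length(sh) / ng, 1),
       byCategory = table(disc$category[qh]))
}

#' Gap bridging by optical map segments
#'
#' A sequence gap is bridged when a single contig's aligned footprint (a
#' map segment, which never crosses a contig boundary spacer) covers both
#' of its flanks.
#'
#' @param segments segment table (chrom, seqStart, seqEnd).
#' @param gaps gap data.frame (name, start, end), 0-based half-open.
#' @param minGap only gaps at least this long are considered (default 2 kb).
#' @return list(nGaps, nBridged, percent).
#' @export
gapBridging <- function(segments, gaps, minGap = 2000) {
  gaps <- gaps[gaps$end - gaps$start >= minGap, , drop = FALSE]
  n <- nrow(gaps)
  if (n == 0) return(list(nGaps = 0L, nBridged = 0L, percent = NA_real_))
  bridged <- vapply(seq_len(n), function(k) {
    any(segments$chrom == gaps$name[k] &
        segments$seqStart < gaps$start[k] &
        segments$seqEnd > gaps$end[k])
  }, logical(1))
  list(nGaps = n, nBridged = sum(bridged),
       percent = round(100 * sum(bridged) / n, 1))
}

#' Export discordance calls
#'
#' Writes a BED-like TSV (chrom, start, end, category, size difference,
#' subtype), ordered by (chrom, start, category), plus a Circos-ready link
#' file for IT events.
#'
#' @param disc discordance data.frame (optionally including IT rows with an
#'   optChrom column).
#' @param path output TSV path; the link file is written alongside with
#'   suffix "_links.txt".
#' @export
exportDiscordances <- function(disc, path) {
  cols <- c("chrom", "seqStart", "seqEnd", "category", "sizeDiff", "subtype")
  d <- disc[order(disc$chrom, disc$seqStart, disc$category), , drop = FALSE]
  write.table(d[, cols, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  links <- d[d$category == "IT", , drop = FALSE]
  linkPath <- sub("\\.tsv$", "", path)
  linkPath <- paste0(linkPath, "_links.txt")
  con <- file(linkPath, "w")
  if (nrow(links) && "optChrom" %in% names(links)) {
    for (k in seq_len(nrow(links)))
      writeLines(sprintf("%s %d %d %s %d %d", links$chrom[k],
                         round(links$seqStart[k]), round(links$seqEnd[k]),
                         links$optChrom[k], round(links$optStart[k]),
                         round(links$optEnd[k])), con)
  }
  close(con)
  invisible(path)
}

#' Read back an exported discordance TSV
#'
#' @param path TSV written by \code{\link{exportDiscordances}}.
#' @export
readDiscordances <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
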