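# Alignment of ordered restriction maps: Rmap -> reference fitting
# alignment, map <-> map local alignment, pile construction, and
# build evaluation by aligned coverage.

#' Score one matched block
#'
#' \code{score = matchBonus - (x - y)^2 / (2 * sizingVarPerBp * max(x,
#' sizingFloor)) - cutPenalty * interiorSites}: a Gaussian sizing likelihood
#' surrogate with variance proportional to reference block length, plus a
#' linear penalty for unmatched interior sites.
#'
#' @param x reference-side block length (bp).
#' @param y query-side block length (bp).
#' @param interiorSites unmatched interior cut sites within the block.
#' @param p an \linkS4class{AlignmentParams}.
#' @export
scoreBlock <- function(x, y, interiorSites = 0, p = alignParams()) {
  stopifnot(all(x > 0), all(y > 0))
  p@matchBonus - (x - y)^2 / (2 * p@sizingVarPerBp * pmax(x, p@sizingFloor)) -
    p@cutPenalty * interiorSites
}

# Build an Alignment object from DP blocks (query indices in aligned
# orientation). qf/rf are the fragment vectors used by the DP.
.mk_alignment <- function(qid, rid, orientation, blocks, qf, rf, score) {
  b <- as.data.frame(blocks)
  names(b) <- c("qs", "qe", "rs", "re")
  Qc <- c(0, cumsum(qf)); Rc <- c(0, cumsum(rf))
  b$refLen <- Rc[b$re + 1] - Rc[b$rs]
  b$qryLen <- Qc[b$qe + 1] - Qc[b$qs]
  b$dev <- b$refLen - b$qryLen
  b$interior <- (b$qe - b$qs) + (b$re - b$rs)
  new("Alignment", queryId = qid, refId = rid, orientation = orientation,
      blocks = b, score = score,
      matchedSites = as.integer(nrow(b) - 1L),
      missedCuts = as.integer(sum(b$re - b$rs)),
      extraCuts = as.integer(sum(b$qe - b$qs)),
      refStart = Rc[b$rs[1]], refEnd = Rc[b$re[nrow(b)] + 1])
}

#' Fitting alignment of an Rmap onto a reference map
#'
#' Dynamic programming over block decompositions bounded by \code{delta}
#' fragments per side.  The entire Rmap interior is consumed; end fragments
#' (shear artifacts) may match partially, and fragments overhanging a
#' reference end are clipped without penalty.  Both orientations are tried;
#' ties break to the leftmost reference start, then to '+'.
#'
#' @param rmap query \linkS4class{FragmentMap}.
#' @param reference reference FragmentMap.
#' @param p an \linkS4class{AlignmentParams}.
#' @return the best \linkS4class{Alignment}, or NULL when the best score is
#'   below \code{minScore} or fewer than \code{minAlignedFragments} query
#'   fragments align (absence is a value, not an error).
#' @export
alignRmap <- function(rmap, reference, p = alignParams()) {
  qf <- fragments(rmap); rf <- fragments(reference)
  if (!length(qf) || !length(rf)) stop("empty map")
  cand <- list()
  for (ori in c("+", "-")) {
    qo <- if (ori == "+") qf else rev(qf)
    res <- cpp_fit_align(qo, rf, as.integer(p@delta), p@matchBonus,
                         p@cutPenalty, p@sizingVarPerBp, p@sizingFloor)
    if (!is.finite(res$score)) next
    bl <- res$blocks
    nq <- bl[nrow(bl), 2] - bl[1, 1] + 1L
    if (res$score < p@minScore || nq < p@minAlignedFragments) next
    # consensus references carry their own measurement noise; the expected
    # per-fragment score against them is correspondingly lower, and low-
    # depth seed maps lower still
    relax <- 0
    lowDepthRef <- FALSE
    if (mapKind(reference) == "consensus") {
      relax <- 0.12
      if (is(reference, "ConsensusMap") &&
          mean(reference@depth) < 35) {
        # below full assembly depth the reference's own sizing error is a
        # sizeable share of the deviation budget
        relax <- 0.45
        lowDepthRef <- TRUE
      }
    }
    if (res$score / nq < p@minScorePerFragment - relax) next
    a <- .mk_alignment(mapId(rmap), mapId(reference), ori, bl, qo, rf,
                       res$score)
    # sizing-drift rejection: a molecule must not be stretched or
    # compressed beyond what measurement error can produce -- checked on
    # every window of interior blocks and on the whole molecule, since a
    # structural difference in the reference can be smeared thinly across
    # many blocks (end blocks are shear-affected and exempt)
    nb <- nrow(a@blocks)
    if (nb > 2L && !lowDepthRef) {
      ib <- a@blocks[2:(nb - 1L), , drop = FALSE]
      nI <- nrow(ib)
      vb <- p@sizingVarPerBp * pmax(ib$refLen, p@sizingFloor)
      cumd <- c(0, cumsum(ib$dev)); cumv <- c(0, cumsum(vb))
      bad <- FALSE
      for (w in seq_len(min(12L, nI))) {
        S <- cumd[(1 + w):(nI + 1)] - cumd[1:(nI + 1 - w)]
        V <- cumv[(1 + w):(nI + 1)] - cumv[1:(nI + 1 - w)]
        if (any(abs(S) > pmax(8000, p@maxDevSigma * sqrt(V)))) {
          bad <- TRUE; break
        }
      }
      if (!bad && abs(cumd[nI + 1]) >
          max(8000, p@maxDevSigma * sqrt(cumv[nI + 1]))) bad <- TRUE
      if (bad) next
    }
    cand[[ori]] <- a
  }
  if (!length(cand)) return(NULL)
  if (length(cand) == 1L) return(cand[[1]])
  s <- vapply(cand, slot, numeric(1), "score")
  if (abs(s[1] - s[2]) > 1e-9) return(cand[[which.max(s)]])
  st <- vapply(cand, slot, numeric(1), "refStart")
  if (abs(st[1] - st[2]) > 1e-9) return(cand[[which.min(st)]])
  cand[["+"]]
}

#' All maximal local alignments between two maps
#'
#' Best-first extraction with overlap masking: the best-scoring local
#' alignment (over both orientations of \code{b}) is extracted, its
#' fragments are masked on both maps, and the search repeats until no
#' alignment reaches \code{minScore}.  Spacer (gap-flagged) fragments are
#' masked from the outset.  Block indices refer to \code{a} (rs, re) and to
#' \code{b} in the aligned orientation (qs, qe); \code{a} plays the
#' reference role in scoring.
#'
#' @param a reference-side FragmentMap.
#' @param b query-side FragmentMap.
#' @param p an \linkS4class{AlignmentParams}.
#' @param minAlignedFragments acceptance floor on aligned \code{b} fragments
#'   (defaults to the value in \code{p}).
#' @param maxAlignments safety cap on extracted alignments.
#' @param orientations which orientations of \code{b} to consider.
#' @param maskA,maskB optional logical vectors marking fragments excluded
#'   from any block (in addition to spacer flags).
#' @return list of \linkS4class{Alignment} (possibly empty), best first.
#' @export
alignMapPair <- function(a, b, p = alignParams(),
                         minAlignedFragments = p@minAlignedFragments,
                         maxAlignments = 64L, orientations = c("+", "-"),
                         maskA = NULL, maskB = NULL) {
  af <- fragments(a); bf <- fragments(b)
  if (is.null(maskA)) maskA <- gapFlags(a) else maskA <- maskA | gapFlags(a)
  if (is.null(maskB)) maskB <- gapFlags(b) else maskB <- maskB | gapFlags(b)
  out <- list()
  repeat {
    best <- NULL; bestOri <- NULL
    for (ori in orientations) {
      bo <- if (ori == "+") bf else rev(bf)
      mo <- if (ori == "+") maskB else rev(maskB)
      res <- cpp_local_align(af, bo, maskA, mo, as.integer(p@delta),
                             p@matchBonus, p@cutPenalty, p@sizingVarPerBp,
                             p@sizingFloor)
      if (!is.finite(res$score) || res$score < p@minScore) next
      bl <- res$blocks
      nq <- bl[nrow(bl), 4] - bl[1, 3] + 1L
      if (nq < minAlignedFragments) next
      if (is.null(best) || res$score > best$score + 1e-9) {
        best <- res; bestOri <- ori
      }
    }
    if (is.null(best)) break
    bl <- best$blocks
    bo <- if (bestOri == "+") bf else rev(bf)
    # cpp_local_align returns (as, ae, bs, be); reorder to (qs, qe, rs, re)
    qb <- cbind(bl[, 3], bl[, 4], bl[, 1], bl[, 2])
    aln <- .mk_alignment(mapId(b), mapId(a), bestOri, qb, bo, af, best$score)
    out[[length(out) + 1L]] <- aln
    # mask consumed fragments on both maps
    maskA[bl[1, 1]:bl[nrow(bl), 2]] <- TRUE
    bidx <- bl[1, 3]:bl[nrow(bl), 4]
    if (bestOri == "-") bidx <- length(bf) + 1L - bidx
    maskB[bidx] <- TRUE
    if (length(out) >= maxAlignments) break
  }
  out
}

#' Align every Rmap of a set to one or more reference maps
#'
#' @param rmaps an RmapSet.
#' @param references a FragmentMap or list of them; each Rmap keeps its best
#'   accepted alignment across references.
#' @param p AlignmentParams.
#' @return named list (by Rmap id) of Alignment; unaligned Rmaps absent.
#' @export
alignRmapSet <- function(rmaps, references, p = alignParams()) {
  if (is(references, "FragmentMap")) references <- list(references)
  out <- list()
  for (m in rmapList(rmaps)) {
    best <- NULL
    for (ref in references) {
      a <- alignRmap(m, ref, p)
      if (!is.null(a) && (is.null(best) || a@score > best@score)) best <- a
    }
    if (!is.null(best)) out[[mapId(m)]] <- best
  }
  out
}

#' Build piles and a depth profile from alignments
#'
#' @param alignments list of \linkS4class{Alignment} against one reference.
#' @param reference the reference FragmentMap.
#' @return list(piles = data.frame(firstFrag, lastFrag, startBp, endBp, n),
#'   depth = per-fragment alignment count).
#' @export
buildPiles <- function(alignments, reference) {
  nf <- nFragments(reference)
  depth <- integer(nf)
  for (a in alignments) {
    if (a@refId != mapId(reference)) stop("alignment references another map")
    lo <- a@blocks$rs[1]; hi <- a@blocks$re[nrow(a@blocks)]
    depth[lo:hi] <- depth[lo:hi] + 1L
  }
  covered <- depth >= 1L
  bp <- c(0, cumsum(fragments(reference)))
  piles <- NULL
  if (any(covered)) {
    r <- rle(covered)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values
    piles <- data.frame(firstFrag = starts[keep], lastFrag = ends[keep])
    piles$startBp <- bp[piles$firstFrag]
    piles$endBp <- bp[piles$lastFrag + 1L]
    piles$n <- vapply(seq_len(nrow(piles)), function(k) {
      sum(vapply(alignments, function(a) {
        a@blocks$rs[1] <= piles$lastFrag[k] &&
          a@blocks$re[nrow(a@blocks)] >= piles$firstFrag[k]
      }, logical(1)))
    }, numeric(1))
  } else {
    piles <- data.frame(firstFrag = integer(0), lastFrag = integer(0),
                        startBp = numeric(0), endBp = numeric(0),
                        n = numeric(0))
  }
  list(piles = piles, depth = depth)
}

#' Evaluate a sequence build by aligned Rmap coverage
#'
#' Aligns every Rmap against the build's map and reports the fraction with
#' an accepted alignment and the length-weighted mean aligned depth -- the
#' comparison that separates a good build from a misassembled one.
#'
#' @param rmaps RmapSet.
#' @param reference the build's in silico FragmentMap.
#' @param p AlignmentParams.
#' @return list(fractionAligned, meanDepth, alignments).
#' @export
evaluateBuild <- function(rmaps, reference, p = alignParams()) {
  alns <- alignRmapSet(rmaps, reference, p)
  pd <- buildPiles(alns, reference)
  w <- fragments(reference)
  list(fractionAligned = length(alns) / length(rmaps),
       meanDepth = sum(pd$depth * w) / sum(w),
       alignments = alns)
}

#' Locally-registered cut agreement between two maps
#'
#' Aligns \code{qry} to \code{ref}, registers matched cut pairs with a
#' rolling local offset (window median), and reports per-cut deviations:
#' for every reference cut inside the aligned footprint, the distance to
#' the nearest query cut after local registration, and vice versa.  This is
#' the evaluation used to ask "does this consensus recover the truth cuts"
#' without crediting or penalizing slow coordinate drift between frames.
#'
#' @param ref reference-side FragmentMap (e.g. the truth map).
#' @param qry query-side FragmentMap (e.g. a consensus contig).
#' @param p AlignmentParams.
#' @param window local registration window bp (default 100 kb).
#' @return list(refDev, qryDev = per-cut deviations in bp (NA outside the
#'   aligned footprint), refCovered = logical per ref cut, footprintBp).
#' @export
mapAgreement <- function(ref, qry, p = alignParams(), window = 1e5) {
  alns <- alignMapPair(ref, qry, p)
  Rb <- c(0, cumsum(fragments(ref)))
  nR <- nFragments(ref)
  refCutPos <- if (nR > 1) Rb[2:nR] else numeric(0)
  refDev <- rep(NA_real_, length(refCutPos))
  qf0 <- fragments(qry)
  nQ <- length(qf0)
  qryCutPosOrig <- if (nQ > 1) cumsum(qf0)[1:(nQ - 1)] else numeric(0)
  qryDev <- rep(NA_real_, length(qryCutPosOrig))
  footprint <- 0
  for (a in alns) {
    qf <- if (a@orientation == "-") rev(qf0) else qf0
    Qb <- c(0, cumsum(qf))
    b <- a@blocks
    qb <- c(b$qs - 1L, b$qe); rb <- c(b$rs - 1L, b$re)
    keep <- qb >= 1 & qb <= nQ - 1 & rb >= 1 & rb <= nR - 1
    qb <- qb[keep]; rb <- rb[keep]
    if (length(qb) < 2) next
    rpos <- Rb[rb + 1L]; qpos <- Qb[qb + 1L]
    d <- rpos - qpos
    off_at <- function(x) median(d[abs(rpos - x) <= window])
    lo <- a@refStart; hi <- a@refEnd
    footprint <- footprint + (hi - lo)
    # all qry cuts inside this footprint, registered locally
    qin <- which(Qb[2:nQ] >= min(qpos) - window & Qb[2:nQ] <= max(qpos) + window)
    for (qi in qin) {
      x <- Qb[qi + 1L]
      proj <- x + off_at(x + median(d))
      dev <- min(abs(refCutPos - proj))
      oi <- if (a@orientation == "-") nQ - qi else qi
      if (is.na(qryDev[oi]) || dev < qryDev[oi]) qryDev[oi] <- dev
    }
    rin <- which(refCutPos >= lo & refCutPos <= hi)
    qproj <- Qb[2:nQ] + vapply(Qb[2:nQ] + median(d), off_at, numeric(1))
    for (ri in rin) {
      dev <- min(abs(qproj - refCutPos[ri]))
      if (is.na(refDev[ri]) || dev < refDev[ri]) refDev[ri] <- dev
    }
  }
  list(refDev = refDev, qryDev = qryDev,
       refCovered = !is.na(refDev), footprintBp = footprint)
}
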