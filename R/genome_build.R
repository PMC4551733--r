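# Chromosome-wide map construction: ordering/orienting contigs on a
# sequence build, stitching with 500 kb spacers, map-segment extraction
# with Table-2-style statistics, and chromosome-end detection/extension.

#' Order and orient contigs against a sequence build
#'
#' Each contig is placed at its best-scoring local map alignment against the
#' per-chromosome in silico maps (ties to the leftmost placement, then '+').
#' Contigs with no accepted alignment are left unplaced and reported.
#'
#' @param contigs list of ConsensusMap (or FragmentMap).
#' @param buildMaps named list of per-chromosome in silico FragmentMaps.
#' @param p AlignmentParams.
#' @return data.frame(contigId, chrom, offset, strand, score); unplaced
#'   contig ids in attribute "unplaced".
#' @export
orderAndOrient <- function(contigs, buildMaps, p = alignParams()) {
  rows <- list(); unplaced <- character(0)
  for (cm in contigs) {
    best <- NULL; bestChrom <- NULL
    for (chrom in names(buildMaps)) {
      alns <- alignMapPair(buildMaps[[chrom]], cm, p, maxAlignments = 1L)
      if (!length(alns)) next
      a <- alns[[1]]
      if (is.null(best) || a@score > best@score + 1e-9 ||
          (abs(a@score - best@score) <= 1e-9 && a@refStart < best@refStart)) {
        best <- a; bestChrom <- chrom
      }
    }
    if (is.null(best)) { unplaced <- c(unplaced, mapId(cm)); next }
    off <- .pair_offset(best, buildMaps[[bestChrom]], cm)
    rows[[length(rows) + 1L]] <- data.frame(
      contigId = mapId(cm), chrom = bestChrom, offset = off,
      strand = best@orientation, score = best@score)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contigId = character(0), chrom = character(0),
               offset = numeric(0), strand = character(0),
               score = numeric(0))
  attr(out, "unplaced") <- unplaced
  out
}

#' Stitch placed contigs into a chromosome-wide map
#'
#' Contig maps are concatenated in placement order with a single gap-flagged
#' spacer fragment (default 500 kb) between consecutive contigs; minus-strand
#' contigs are reversed.  Spacer fragments are flagged so downstream
#' alignment treats them as unalignable and fragment statistics exclude
#' them.
#'
#' @param placed placement rows for one chromosome (from
#'   \code{\link{orderAndOrient}}).
#' @param contigs the contig list the placements refer to.
#' @param spacer spacer length bp (default 500 kb).
#' @param chrom chromosome name for the output map id.
#' @param onOverlap "error" stops on overlapping placements listing the
#'   pair; "drop" keeps the higher-scoring contig; "trim" removes fragments
#'   from the lower-scoring contig's facing end until the overlap clears.
#' @return list(map = FragmentMap kind "chromosome", layout = data.frame
#'   (contigId, startBp, endBp, strand) in chromosome-map coordinates,
#'   depth = per-fragment consensus depth (0 on spacers), junctions =
#'   per-junction placement deltas on the build (negative = the flanking
#'   contigs' placements overlapped before trimming)).
#' @export
stitchChromosome <- function(placed, contigs, spacer = 5e5,
                             chrom = unique(placed$chrom),
                             onOverlap = c("error", "drop", "trim")) {
  onOverlap <- match.arg(onOverlap)
  stopifnot(nrow(placed) >= 1, length(chrom) == 1)
  byid <- setNames(contigs, vapply(contigs, mapId, character(1)))
  byid0 <- byid
  placed <- placed[order(placed$offset), , drop = FALSE]
  spans <- vapply(placed$contigId, function(id) mapSpan(byid[[id]]),
                  numeric(1))
  repeat {
    ends <- placed$offset + spans
    bad <- which(head(ends, -1) > tail(placed$offset, -1))
    if (!length(bad)) break
    i <- bad[1]
    if (onOverlap == "error")
      stop(sprintf("overlapping placements: %s and %s on %s",
                   placed$contigId[i], placed$contigId[i + 1], chrom))
    weaker <- if (placed$score[i] >= placed$score[i + 1]) i + 1L else i
    if (onOverlap == "drop" ||
        ends[i] - placed$offset[i + 1] >= 0.9 * spans[weaker]) {
      placed <- placed[-weaker, , drop = FALSE]
      spans <- spans[-weaker]
      next
    }
    # trim whole fragments off the weaker contig's facing end
    ov <- ends[i] - placed$offset[i + 1]
    id <- placed$contigId[weaker]
    cm <- byid[[id]]
    f <- fragments(cm)
    fromLeft <- xor(weaker == i + 1L, placed$strand[weaker] == "-")
    keepIdx <- if (fromLeft) {
      k <- which(cumsum(f) >= ov)[1]
      if (weaker == i + 1L && placed$strand[weaker] == "+")
        placed$offset[weaker] <- placed$offset[weaker] + sum(f[1:k])
      setdiff(seq_along(f), 1:k)
    } else {
      k <- which(rev(cumsum(rev(f))) >= ov)
      k <- k[length(k)]
      if (weaker == i + 1L && placed$strand[weaker] == "-")
        placed$offset[weaker] <- placed$offset[weaker] +
          (sum(f) - sum(f[seq_len(k - 1L)]))
      seq_len(k - 1L)
    }
    cm@fragments <- f[keepIdx]
    if (length(cm@gapFlags)) cm@gapFlags <- cm@gapFlags[keepIdx]
    if (is(cm, "ConsensusMap")) {
      cm@depth <- cm@depth[keepIdx]
      cm@spread <- cm@spread[keepIdx]
    }
    if (length(cm@fragments) < 2L) {
      placed <- placed[-weaker, , drop = FALSE]
      spans <- spans[-weaker]
      next
    }
    byid[[id]] <- cm
    spans[weaker] <- mapSpan(cm)
  }
  # placement geometry on the build is evidence in itself: overlapping
  # placements mean the optical maps carry more material than the build
  # (missing sequence), a placement gap means extraneous build sequence
  spanOrig <- vapply(placed$contigId, function(id) mapSpan(byid0[[id]]),
                     numeric(1))
  jdelta <- if (nrow(placed) > 1L)
    placed$offset[-1] - (head(placed$offset, -1) + head(spanOrig, -1))
  else numeric(0)
  frags <- numeric(0); flags <- logical(0); depth <- numeric(0)
  layout <- list()
  pos <- 0
  for (k in seq_len(nrow(placed))) {
    if (k > 1L) {
      frags <- c(frags, spacer); flags <- c(flags, TRUE)
      depth <- c(depth, 0)
      pos <- pos + spacer
    }
    cm <- byid[[placed$contigId[k]]]
    f <- fragments(cm)
    dd <- if (is(cm, "ConsensusMap")) cm@depth else rep(NA_real_, length(f))
    if (placed$strand[k] == "-") { f <- rev(f); dd <- rev(dd) }
    frags <- c(frags, f); flags <- c(flags, rep(FALSE, length(f)))
    depth <- c(depth, dd)
    layout[[k]] <- data.frame(contigId = placed$contigId[k], startBp = pos,
                              endBp = pos + sum(f),
                              strand = placed$strand[k])
    pos <- pos + sum(f)
  }
  map <- FragmentMap(paste0(chrom, "_OM"), frags, kind = "chromosome",
                     gapFlags = flags,
                     origin = list(source = chrom, start = 0, end = pos,
                                   strand = "+"))
  lay <- do.call(rbind, layout)
  junctions <- if (nrow(lay) > 1L)
    data.frame(optPos = head(lay$endBp, -1) + spacer / 2,
               placementDelta = jdelta)
  else data.frame(optPos = numeric(0), placementDelta = numeric(0))
  list(map = map, layout = lay, depth = depth, junctions = junctions)
}

#' Extract aligned map segments between a chromosome map and a build
#'
#' A map segment is a maximal run of contiguous restriction fragments that
#' aligns between the optical chromosome map and the build's in silico map.
#' Local alignments never cross spacer fragments (they are masked) and
#' break at discordance breakpoints, so each accepted alignment is one
#' segment.
#'
#' @param chromMap optical chromosome FragmentMap (gap-flagged spacers).
#' @param buildMap the chromosome's in silico FragmentMap.
#' @param p AlignmentParams.
#' @param chrom chromosome name.
#' @param chromSize denominator for percent coverage (default: build map
#'   span, i.e. the sequence length).
#' @return list(segments = data.frame(chrom, seqStart, seqEnd, optStart,
#'   optEnd, orientation, nFrags, massBp), stats = one-row data.frame
#'   (chrom, nSegments, meanSizeMb, totalMassMb, pctCoverage)).
#' @export
extractMapSegments <- function(chromMap, buildMap, p = alignParams(),
                               chrom = mapId(buildMap),
                               chromSize = mapSpan(buildMap)) {
  rs <- .resolveStructure(buildMap, chromMap, p)
  if (length(rs$extras)) {
    maskA <- rep(FALSE, nFragments(buildMap))
    for (m in rs$extras)
      maskA[m@blocks$rs[1]:m@blocks$re[nrow(m@blocks)]] <- TRUE
    alns <- c(alignMapPair(buildMap, chromMap, p, maskA = maskA),
              rs$extras)
  } else {
    alns <- alignMapPair(buildMap, chromMap, p)
  }
  nOpt <- nFragments(chromMap)
  optB <- c(0, cumsum(fragments(chromMap)))
  segs <- lapply(alns, function(a) {
    b <- a@blocks
    qlo <- b$qs[1]; qhi <- b$qe[nrow(b)]
    if (a@orientation == "-") { tmp <- qlo; qlo <- nOpt + 1L - qhi
                                qhi <- nOpt + 1L - tmp }
    data.frame(chrom = chrom, seqStart = a@refStart, seqEnd = a@refEnd,
               optStart = optB[qlo], optEnd = optB[qhi + 1L],
               orientation = a@orientation,
               nFrags = nrow(b) + sum(b$re - b$rs),
               massBp = a@refEnd - a@refStart)
  })
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(0), seqStart = numeric(0),
               seqEnd = numeric(0), optStart = numeric(0),
               optEnd = numeric(0), orientation = character(0),
               nFrags = integer(0), massBp = numeric(0))
  segments <- segments[order(segments$seqStart), , drop = FALSE]
  stats <- data.frame(chrom = chrom, nSegments = nrow(segments),
                      meanSizeMb = if (nrow(segments))
                        sum(segments$massBp) / nrow(segments) / 1e6 else 0,
                      totalMassMb = sum(segments$massBp) / 1e6,
                      pctCoverage = 100 * sum(segments$massBp) / chromSize)
  list(segments = segments, stats = stats)
}

#' Detect chromosome ends from molecule-end pile-ups
#'
#' An end is flagged as a chromosome end when at least \code{minEnders}
#' member molecules terminate within \code{window} bp of the contig
#' terminus while the interior depth at 2x the window is at least
#' \code{minDepth}: a pile-up random shearing cannot produce.
#'
#' @param contig a ConsensusMap with member poses.
#' @param minEnders molecule-end count threshold (default 10).
#' @param window terminus window bp (default 30 kb).
#' @param minDepth required interior depth (default 20).
#' @return named logical c(left=, right=).
#' @export
detectChromosomeEnds <- function(contig, minEnders = 10, window = 3e4,
                                 minDepth = 20) {
  poses <- contig@memberPoses
  if (length(poses) < minEnders) return(c(left = FALSE, right = FALSE))
  starts <- vapply(poses, `[[`, numeric(1), "start")
  ends <- vapply(poses, `[[`, numeric(1), "end")
  # molecules truncated at a real chromosome end share one extreme
  # boundary; random shearing spreads boundaries at coverage/moleculeLength
  # per bp, far below the pile-up density
  s0 <- min(starts); e0 <- max(ends)
  nL <- sum(starts <= s0 + window)
  nR <- sum(ends >= e0 - window)
  covL <- sum(starts <= s0 + 2 * window & ends >= s0 + 2 * window)
  covR <- sum(starts <= e0 - 2 * window & ends >= e0 - 2 * window)
  c(left = nL >= minEnders && covL >= minDepth,
    right = nR >= minEnders && covR >= minDepth)
}

#' Optical extension beyond the sequence termini
#'
#' For each chromosome end, the optical map mass lying outside the terminal
#' aligned segment, in excess of the unaligned sequence mass on that side;
#' 0 when the sequence reaches or passes the optical terminus.
#'
#' @param chromMap optical chromosome map.
#' @param buildMap sequence chromosome map.
#' @param segments segment table from \code{\link{extractMapSegments}}.
#' @return data.frame(end = c("left", "right"), extensionBp).
#' @export
endExtension <- function(chromMap, buildMap, segments) {
  if (!nrow(segments))
    return(data.frame(end = c("left", "right"), extensionBp = c(0, 0)))
  segments <- segments[order(segments$seqStart), , drop = FALSE]
  first <- segments[1, ]; last <- segments[nrow(segments), ]
  extL <- max(0, first$optStart - first$seqStart)
  extR <- max(0, (mapSpan(chromMap) - last$optEnd) -
                 (mapSpan(buildMap) - last$seqEnd))
  data.frame(end = c("left", "right"), extensionBp = c(extL, extR))
}
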