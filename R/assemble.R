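# Reference-seeded iterative assembly: posing molecules from alignments,
# cut clustering and consensus construction, 1 Mb / 500 kb binning,
# alignment<->assembly cycles, contig merging, and Table-1-style statistics.

#' Pose a molecule in its reference frame
#'
#' Converts an accepted fitting alignment into a placement of the molecule's
#' cut positions in reference coordinates.  The molecule is anchored with a
#' single offset (the median of reference-minus-query positions over matched
#' interior cuts), so within-molecule distances stay the molecule's own
#' measurements and overhanging ends project beyond the reference.
#'
#' @param rmap the molecule.
#' @param aln its \linkS4class{Alignment} to the reference.
#' @param reference the reference map the alignment refers to.
#' @return list(id, start, end, cuts) in reference bp.
#' @export
poseFromAlignment <- function(rmap, aln, reference) {
  qf <- fragments(rmap)
  if (aln@orientation == "-") qf <- rev(qf)
  .project_pose(mapId(rmap), qf, fragments(reference), aln@blocks)
}

# Piecewise projection of a molecule's boundaries into the frame of the map
# it is aligned to: matched block boundaries take the frame coordinate of
# their matched cut exactly; unmatched boundaries (false cuts, overhangs)
# anchor to the nearest matched boundary plus the measured distance.  The
# molecule's own measured cut coordinates are kept alongside (mcuts) so
# consensus spreads reflect real sizing measurements.
.project_pose <- function(id, qf, rf, blocks) {
  m <- length(qf)
  Qb <- c(0, cumsum(qf))
  Rb <- c(0, cumsum(rf))
  qb <- c(blocks$qs - 1L, blocks$qe)      # matched boundary indices (0..m)
  rb <- c(blocks$rs - 1L, blocks$re)
  dup <- duplicated(qb)
  qb <- qb[!dup]; rb <- rb[!dup]
  # the alignment's outermost boundaries close end blocks, which may be
  # free/partial (molecule shear, reference end): they are not measured cut
  # correspondences and must not snap -- molecule ends project locally
  if (length(qb) > 2L) {
    o <- order(qb)
    qb <- qb[o]; rb <- rb[o]
    keep <- seq_along(qb)[-c(1L, length(qb))]
    qb <- qb[keep]; rb <- rb[keep]
  }
  proj <- numeric(m + 1L)
  for (c in 0:m) {
    hit <- match(c, qb)
    if (!is.na(hit)) proj[c + 1L] <- Rb[rb[hit] + 1L]
    else {
      k <- which.min(abs(qb - c))
      proj[c + 1L] <- Rb[rb[k] + 1L] + (Qb[c + 1L] - Qb[qb[k] + 1L])
    }
  }
  list(id = id, start = proj[1L], end = proj[m + 1L],
       cuts = if (m > 1L) proj[2:m] else numeric(0),
       mcuts = if (m > 1L) Qb[2:m] else numeric(0))
}

# single-linkage clustering of sorted positions: gap > radius splits
.cluster_chain <- function(pos, radius) {
  if (!length(pos)) return(integer(0))
  c(0L, cumsum(diff(pos) > radius)) + 1L
}

# coverage (number of posed members spanning p) for a vector of positions
.coverage_at <- function(p, starts, ends) {
  findInterval(p, sort(starts)) - findInterval(p, sort(ends))
}

#' Build consensus maps from posed molecules
#'
#' Cut events from all posed members are pooled and clustered by
#' single-linkage with a fixed radius; a cluster becomes a consensus cut
#' when it is supported by at least \code{supportFrac} of the molecules
#' spanning its position (and by at least two molecules).  Cut positions are
#' cluster medians; regions where molecule coverage drops below
#' \code{minDepth} are trimmed at the ends and split in the interior.
#' Per-fragment depth is the spanning-molecule count and per-fragment spread
#' the standard deviation of member-measured inter-cut distances.
#'
#' @param poses list of poses (see \code{\link{poseFromAlignment}}).
#' @param minDepth minimum molecule depth retained (default 20).
#' @param radius cut-clustering radius in bp (default 2000, about 1.5x the
#'   default sizing SD).
#' @param supportFrac fraction of spanning molecules that must carry a cut.
#' @param idPrefix identifier prefix for emitted contigs.
#' @param enzyme enzyme label.
#' @param anchors optional cut grid of the posing frame guiding cluster
#'   assignment.
#' @param refineSizes re-estimate fragment lengths as the median of member
#'   measured inter-cut distances.
#' @param relDepth relative recruitment floor: regions below this fraction
#'   of the median depth split even when above \code{minDepth}; 0 turns
#'   the rule off (used for low-depth seed maps).
#' @return list of \linkS4class{ConsensusMap} (empty when nothing survives).
#' @export
buildConsensusFromPoses <- function(poses, minDepth = 20, radius = 2000,
                                    supportFrac = 0.5, idPrefix = "contig",
                                    enzyme = "BamHI", anchors = NULL,
                                    refineSizes = FALSE, relDepth = 0.55) {
  if (!length(poses)) return(list())
  starts <- vapply(poses, `[[`, numeric(1), "start")
  ends <- vapply(poses, `[[`, numeric(1), "end")
  ncuts <- vapply(poses, function(x) length(x$cuts), integer(1))
  cutpos <- unlist(lapply(poses, `[[`, "cuts"), use.names = FALSE)
  cutmes <- unlist(lapply(poses, function(x)
    if (is.null(x$mcuts)) x$cuts else x$mcuts), use.names = FALSE)
  cutmem <- rep(seq_along(poses), ncuts)
  o <- order(cutpos)
  cutpos <- cutpos[o]; cutmem <- cutmem[o]; cutmes <- cutmes[o]
  if (length(anchors)) {
    # anchor-guided grouping: member cuts within `radius` of the nearest
    # anchor (a cut of the posing frame) group by that anchor; the rest --
    # false cuts and cuts in extension regions -- chain-cluster at a
    # tighter radius to avoid bridging adjacent true-cut clusters
    anchors <- sort(anchors)
    if (length(anchors) > 1L) {   # collapse near-duplicate anchors
      acl <- .cluster_chain(anchors, 0.8 * radius)
      anchors <- as.numeric(tapply(anchors, acl, mean))
    }
    nearest <- findInterval(cutpos, anchors)
    lo <- pmax(nearest, 1L); hi <- pmin(nearest + 1L, length(anchors))
    dlo <- abs(cutpos - anchors[lo]); dhi <- abs(cutpos - anchors[hi])
    aidx <- ifelse(dlo <= dhi, lo, hi)
    adist <- pmin(dlo, dhi)
    anchored <- adist <= radius
    cl <- integer(length(cutpos))
    cl[anchored] <- aidx[anchored]
    if (any(!anchored))
      cl[!anchored] <- length(anchors) +
        .cluster_chain(cutpos[!anchored], 0.6 * radius)
  } else {
    cl <- .cluster_chain(cutpos, radius)
  }
  s_starts <- sort(starts); s_ends <- sort(ends)
  cmed <- tapply(cutpos, cl, median)
  csupp <- tapply(cutmem, cl, function(m) length(unique(m)))
  cspan <- .coverage_at(as.numeric(cmed), s_starts, s_ends)
  keep <- csupp >= pmax(2, supportFrac * cspan)
  cons_cl <- as.integer(names(cmed))[keep]
  cons_pos <- as.numeric(cmed)[keep]
  ord <- order(cons_pos)
  cons_pos <- cons_pos[ord]; cons_cl <- cons_cl[ord]

  # per-cluster member -> measured-position lookup (for spreads)
  memtab <- split(data.frame(pos = cutmes, mem = cutmem), cl)

  # coverage sweep: maximal regions with depth >= minDepth; a sustained
  # collapse of recruitment relative to the dataset's own depth also splits
  # (the molecules are voting against the region, whatever its cause)
  evts <- sort(unique(c(starts, ends)))
  if (length(evts) < 2L) return(list())
  mids <- head(evts, -1) + diff(evts) / 2
  dep <- .coverage_at(mids, s_starts, s_ends)
  thr <- minDepth
  if (relDepth > 0) {
    med <- median(dep[dep > 0])
    thr <- max(minDepth, relDepth * med)
  }
  okseg <- dep >= thr
  if (!any(okseg)) return(list())
  r <- rle(okseg)
  seg_end_idx <- cumsum(r$lengths); seg_start_idx <- seg_end_idx - r$lengths + 1L
  regions <- cbind(evts[seg_start_idx[r$values]],
                   evts[seg_end_idx[r$values] + 1L])

  out <- list()
  for (k in seq_len(nrow(regions))) {
    L <- regions[k, 1]; R <- regions[k, 2]
    sel <- cons_pos > L & cons_pos < R
    cpos <- cons_pos[sel]; ccl <- cons_cl[sel]
    bnd <- c(L, cpos, R)
    if (any(diff(bnd) <= 0)) {
      ok <- c(TRUE, diff(bnd) > 0)
      bnd <- bnd[ok]
      ccl <- ccl[ok[-1][seq_along(ccl)]]
    }
    frags <- diff(bnd)
    if (length(frags) < 5L) next   # degenerate shard, not a consensus map
    # spread (and, when refining, length) from member-measured distances
    # between adjacent consensus clusters
    spr <- numeric(length(frags))
    if (length(ccl) >= 2L) {
      for (f in seq_len(length(ccl) - 1L)) {
        a <- memtab[[as.character(ccl[f])]]
        b <- memtab[[as.character(ccl[f + 1L])]]
        shared <- intersect(a$mem, b$mem)
        if (length(shared) >= 2L) {
          d <- b$pos[match(shared, b$mem)] - a$pos[match(shared, a$mem)]
          d <- d[d > 0]
          if (length(d) >= 2L) {
            spr[f + 1L] <- sd(d)
            if (refineSizes) frags[f + 1L] <- median(d)
          }
        }
      }
      if (refineSizes) bnd <- bnd[1] + c(0, cumsum(frags))
    }
    midp <- head(bnd, -1) + frags / 2
    fdep <- .coverage_at(midp, s_starts, s_ends)
    memsel <- which(ends > L & starts < R)
    mem_ids <- vapply(poses[memsel], `[[`, character(1), "id")
    mposes <- lapply(poses[memsel], function(x)
      list(id = x$id, start = x$start - L, end = x$end - L,
           cuts = x$cuts - L,
           mcuts = if (is.null(x$mcuts)) x$cuts - L else x$mcuts))
    cm <- new("ConsensusMap",
              mapId = sprintf("%s_%02d", idPrefix, k),
              enzyme = enzyme, fragments = as.numeric(frags),
              kind = "consensus",
              origin = list(source = idPrefix, start = L, end = R,
                            strand = "+"),
              depth = as.numeric(fdep), spread = as.numeric(spr),
              members = mem_ids, memberPoses = mposes,
              tandemFlag = .tandem_flagged(frags))
    out[[length(out) + 1L]] <- cm
  }
  out
}

#' Build a consensus map from aligned Rmaps
#'
#' Poses each member from its alignment and delegates to
#' \code{\link{buildConsensusFromPoses}}.
#'
#' @param rmaps RmapSet (or list of FragmentMap).
#' @param alignments named list of alignments (names = Rmap ids) against a
#'   shared reference frame.
#' @param reference the shared reference map.
#' @param minDepth,radius,supportFrac,idPrefix see
#'   \code{\link{buildConsensusFromPoses}}.
#' @return list of ConsensusMap; empty list when nothing reaches minDepth.
#' @export
buildConsensus <- function(rmaps, alignments, reference, minDepth = 20,
                           radius = 2000, supportFrac = 0.5,
                           idPrefix = "contig", refineSizes = TRUE) {
  maps <- if (is(rmaps, "RmapSet")) rmapList(rmaps) else rmaps
  byid <- setNames(maps, vapply(maps, mapId, character(1)))
  poses <- lapply(names(alignments), function(id)
    poseFromAlignment(byid[[id]], alignments[[id]], reference))
  buildConsensusFromPoses(poses, minDepth = minDepth, radius = radius,
                          supportFrac = supportFrac, idPrefix = idPrefix,
                          anchors = .cuts(reference),
                          refineSizes = refineSizes)
}

# long-tandem-repeat signature: fragment-pattern autocorrelation > 0.9
# at a nonzero lag over a sliding window
.tandem_flagged <- function(frags, maxLag = 10L, minFrags = 40L,
                            threshold = 0.9) {
  n <- length(frags)
  if (n < minFrags) return(FALSE)
  for (lag in seq_len(min(maxLag, n - minFrags %/% 2))) {
    x <- frags[1:(n - lag)]; y <- frags[(1 + lag):n]
    if (sd(x) < 1e-9 || sd(y) < 1e-9) next
    if (stats::cor(x, y) > threshold) return(TRUE)
  }
  FALSE
}

#' Divide posed alignments into overlapping assembly bins
#'
#' Bins tile the reference with width \code{binSize} and stride
#' \code{binSize - overlap}; a molecule joins every bin containing at least
#' half of its footprint.
#'
#' @param poses list of poses in a shared frame.
#' @param binSize bin width bp (default 1 Mb).
#' @param overlap bin overlap bp (default 500 kb).
#' @return list of bins: list(index, start, end, members = pose indices).
#' @export
binAlignments <- function(poses, binSize = 1e6, overlap = 5e5) {
  stopifnot(overlap < binSize)
  if (!length(poses)) return(list())
  stride <- binSize - overlap
  starts <- vapply(poses, `[[`, numeric(1), "start")
  ends <- vapply(poses, `[[`, numeric(1), "end")
  lo <- floor(min(starts) / stride) * stride
  hi <- max(ends)
  binStarts <- seq(lo, max(lo, hi - overlap), by = stride)
  lapply(seq_along(binStarts), function(k) {
    b0 <- binStarts[k]; b1 <- b0 + binSize
    ov <- pmin(ends, b1) - pmax(starts, b0)
    mem <- which(ov >= 0.5 * (ends - starts))
    list(index = k, start = b0, end = b1, members = mem)
  })
}

.n50 <- function(x) {
  if (!length(x)) return(0)
  x <- sort(x, decreasing = TRUE)
  x[which(cumsum(x) >= sum(x) / 2)[1]]
}

#' Iterative (reference-seeded) assembly
#'
#' Cycle 1 aligns the full Rmap set to the initial reference (normally an in
#' silico map of a sequence build), bins the posed molecules (1 Mb bins,
#' 500 kb overlap), and assembles each bin into consensus contigs at a
#' minimum molecule depth.  Every later cycle aligns the full Rmap set to
#' the previous cycle's contigs -- the sequence is no longer used -- letting
#' contigs extend through member overhangs.  Stops early when the total
#' consensus span changes by less than \code{tol} between cycles.
#'
#' @param rmaps RmapSet.
#' @param initialRef FragmentMap or list of FragmentMaps.
#' @param cycles maximum cycles (default 8).
#' @param p AlignmentParams.
#' @param minDepth minimum consensus depth (default 20).
#' @param binSize,overlap assembly binning (default 1 Mb / 500 kb).
#' @param tol early-stop tolerance on total-span change (default 0.001).
#' @return list(contigs, metrics = per-cycle data.frame, recruited =
#'   member ids of the final contigs, alleles = allele-pair tags).
#' @export
iterateAssembly <- function(rmaps, initialRef, cycles = 8,
                            p = alignParams(), minDepth = 20,
                            binSize = 1e6, overlap = 5e5, tol = 0.001,
                            refineSizes = TRUE) {
  stopifnot(cycles >= 1)
  refs <- if (is(initialRef, "FragmentMap")) list(initialRef) else initialRef
  maps <- rmapList(rmaps)
  byid <- setNames(maps, vapply(maps, mapId, character(1)))
  metrics <- list()
  contigs <- list()
  alleles <- data.frame()
  prevSpan <- NA_real_; flat <- 0L
  bestSpan <- -Inf; bestContigs <- list(); bestAlleles <- data.frame()
  for (cyc in seq_len(cycles)) {
    alns <- alignRmapSet(rmaps, refs, p)
    if (!length(alns)) {
      if (!length(bestContigs))
        warning("no Rmap aligned in cycle ", cyc, "; empty assembly")
      break
    }
    refIds <- vapply(refs, mapId, character(1))
    contigs <- list()
    for (ri in seq_along(refs)) {
      ids <- names(alns)[vapply(alns, function(a) a@refId == refIds[ri],
                                logical(1))]
      if (!length(ids)) next
      poses <- lapply(ids, function(id)
        poseFromAlignment(byid[[id]], alns[[id]], refs[[ri]]))
      anchors <- .cuts(refs[[ri]])
      bins <- binAlignments(poses, binSize, overlap)
      binctg <- list()
      for (b in bins) {
        if (!length(b$members)) next
        cc <- buildConsensusFromPoses(poses[b$members], minDepth = minDepth,
                                      anchors = anchors,
                                      refineSizes = refineSizes,
                                      idPrefix = sprintf("c%d_r%d_b%d",
                                                         cyc, ri, b$index))
        binctg <- c(binctg, cc)
      }
      # consolidate overlapping bin contigs within this shared frame:
      # pool member poses of interval-overlapping contigs and rebuild
      if (length(binctg) > 1L) {
        iv <- t(vapply(binctg, function(cm)
          c(cm@origin$start, cm@origin$end), numeric(2)))
        comp <- .interval_components(iv)
        consolidated <- list()
        for (g in unique(comp)) {
          gi <- which(comp == g)
          ids_g <- unique(unlist(lapply(binctg[gi], members)))
          cc <- buildConsensusFromPoses(poses[match(ids_g,
                   vapply(poses, `[[`, character(1), "id"))],
                 minDepth = minDepth, anchors = anchors,
                 refineSizes = refineSizes,
                 idPrefix = sprintf("c%d_r%d_g%d", cyc, ri, g))
          consolidated <- c(consolidated, cc)
        }
        binctg <- consolidated
      }
      contigs <- c(contigs, binctg)
    }
    if (length(contigs) > 1L) {
      mg <- mergeContigs(contigs, p = p, minDepth = minDepth,
                         refineSizes = refineSizes)
      contigs <- mg$contigs
      alleles <- mg$alleles
    }
    spans <- vapply(contigs, mapSpan, numeric(1))
    metrics[[cyc]] <- data.frame(cycle = cyc, nContigs = length(contigs),
                                 totalSpanMb = sum(spans) / 1e6,
                                 meanSpanMb = mean(spans) / 1e6,
                                 n50Mb = .n50(spans) / 1e6)
    if (sum(spans) > bestSpan) {
      bestSpan <- sum(spans); bestContigs <- contigs; bestAlleles <- alleles
    }
    # iterate while the assembly keeps growing (with one cycle of grace:
    # merging can restructure before extension shows); consensus references
    # are noisier than the maps assembled from them, so once growth truly
    # stops, further cycles only erode
    if (sum(spans) < bestSpan * (1 + tol)) {
      flat <- flat + 1L
      if (flat >= 3L) break
    } else flat <- 0L
    prevSpan <- sum(spans)
    refs <- contigs   # sequence information is no longer used
    if (!length(refs)) break
  }
  contigs <- bestContigs
  for (k in seq_along(contigs)) contigs[[k]]@mapId <- sprintf("contig_%03d", k)
  list(contigs = contigs, metrics = do.call(rbind, metrics),
       recruited = unique(unlist(lapply(contigs, members))),
       alleles = bestAlleles)
}

# connected components of interval overlap (n small; quadratic fine)
.interval_components <- function(iv) {
  n <- nrow(iv)
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && iv[i, 1] < iv[j, 2] && iv[j, 1] < iv[i, 2]) {
      a <- find(i); b <- find(j)
      if (a != b) comp[max(a, b)] <- comp[min(a, b)]
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Merge overlapping consensus contigs
#'
#' Contig pairs whose pairwise map alignment overlaps by at least
#' \code{minOverlapFrags} fragments at an accepted score are merged
#' transitively (union-find); the overlap is resolved by pooling the member
#' poses of a component into the frame of its largest contig and re-running
#' consensus construction.  Pairs whose overlap evidence contains two
#' well-supported placements differing by at least \code{alleleIndel} bp are
#' kept separate and cross-tagged as an allele pair (heterozygous indel).
#' Tandem-flagged contigs are excluded from merging but retained.
#'
#' @param contigs list of ConsensusMap.
#' @param p AlignmentParams.
#' @param minDepth consensus depth for the merged rebuild.
#' @param minOverlapFrags minimum aligned fragments to merge (default 10).
#' @param alleleIndel heterozygous-indel size threshold bp (default 40 kb).
#' @param minSharedMembers merge candidates must share at least this many
#'   member Rmaps (coincidental pattern matches share none).
#' @return list(contigs, alleles = data.frame of cross-tagged pairs).
#' @export
mergeContigs <- function(contigs, p = alignParams(), minDepth = 20,
                         minOverlapFrags = 10, alleleIndel = 4e4,
                         refineSizes = TRUE, minSharedMembers = 2) {
  n <- length(contigs)
  alleles <- data.frame(a = character(0), b = character(0),
                        indel = numeric(0))
  if (n <= 1L) return(list(contigs = contigs, alleles = alleles))
  mergeable <- !vapply(contigs, function(cm) isTRUE(cm@tandemFlag), logical(1))
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  edges <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (!mergeable[i] || !mergeable[j]) next
    # genuine overlaps share member molecules; alignment score alone cannot
    # separate true contig overlaps from coincidental pattern matches --
    # unless the overlap is long and essentially penalty-free
    sharedIds <- intersect(members(contigs[[i]]), members(contigs[[j]]))
    alnlist <- alignMapPair(contigs[[i]], contigs[[j]], p,
                            minAlignedFragments = minOverlapFrags,
                            maxAlignments = 4L)
    if (!length(alnlist)) next
    a1 <- alnlist[[1]]
    if (length(sharedIds) >= minSharedMembers) {
      # the shared molecules imply the true relative placement; an overlap
      # alignment that disagrees with it is a coincidental pattern match
      # (e.g. between the facing ends of contigs split at a discordance)
      si <- contigs[[i]]@memberPoses
      names(si) <- vapply(si, `[[`, character(1), "id")
      sj <- contigs[[j]]@memberPoses
      names(sj) <- vapply(sj, `[[`, character(1), "id")
      spanj <- mapSpan(contigs[[j]])
      offs <- vapply(sharedIds, function(id) {
        if (a1@orientation == "+") si[[id]]$start - sj[[id]]$start
        else si[[id]]$start - (spanj - sj[[id]]$end)
      }, numeric(1))
      # the shared molecules must agree among themselves (a mis-posed pair
      # would otherwise forge an edge) and with the overlap alignment
      if (length(offs) < 3L || stats::mad(offs) > 5e3) next
      alnOff <- .pair_offset(a1, contigs[[i]], contigs[[j]])
      if (abs(alnOff - median(offs)) > 1e4) next
    } else {
      nfr <- sum(a1@blocks$qe - a1@blocks$qs + 1L)
      if (nfr < max(25, 2 * minOverlapFrags) ||
          a1@score / nrow(a1@blocks) < 2.5) next
    }
    offs <- vapply(alnlist, function(a)
      .pair_offset(a, contigs[[i]], contigs[[j]]), numeric(1))
    oris <- vapply(alnlist, slot, character(1), "orientation")
    same <- oris == oris[1]
    if (sum(same) >= 2L) {
      gap <- max(offs[same]) - min(offs[same])
      if (gap >= alleleIndel) {
        alleles <- rbind(alleles, data.frame(a = mapId(contigs[[i]]),
                                             b = mapId(contigs[[j]]),
                                             indel = gap))
        next
      }
    }
    a1 <- alnlist[[1]]
    edges[[length(edges) + 1L]] <- list(i = i, j = j, offset = offs[1],
                                        orientation = a1@orientation,
                                        score = a1@score)
    a <- find(i); b <- find(j)
    if (a != b) comp[max(a, b)] <- comp[min(a, b)]
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (g in unique(comp)) {
    gi <- which(comp == g)
    if (length(gi) == 1L) { out <- c(out, contigs[gi]); next }
    # frame = largest contig; BFS over merge edges to place the others
    placement <- .component_placement(gi, edges, contigs)
    pooled <- list()
    for (ci in gi) {
      pl <- placement[[as.character(ci)]]
      if (is.null(pl)) next
      span <- mapSpan(contigs[[ci]])
      for (ps in contigs[[ci]]@memberPoses) {
        mc <- if (is.null(ps$mcuts)) ps$cuts else ps$mcuts
        if (pl$flip) {
          msum <- ps$end - ps$start
          ps <- list(id = ps$id, start = span - ps$end, end = span - ps$start,
                     cuts = rev(span - ps$cuts))
          mc <- rev(msum - mc)
        }
        pooled[[length(pooled) + 1L]] <-
          list(id = ps$id, start = ps$start + pl$offset,
               end = ps$end + pl$offset, cuts = ps$cuts + pl$offset,
               mcuts = mc)
      }
    }
    # one pose per distinct member (keep the longest placement)
    ids <- vapply(pooled, `[[`, character(1), "id")
    lens <- vapply(pooled, function(x) x$end - x$start, numeric(1))
    keep <- !duplicated(ids[order(-lens)])[order(order(-lens))]
    pooled <- pooled[keep]
    # anchor grid: the component contigs' own consensus cuts, transformed
    anch <- numeric(0)
    for (ci in gi) {
      pl <- placement[[as.character(ci)]]
      if (is.null(pl)) next
      ccut <- .cuts(contigs[[ci]])
      if (pl$flip) ccut <- rev(mapSpan(contigs[[ci]]) - ccut)
      anch <- c(anch, ccut + pl$offset)
    }
    cc <- buildConsensusFromPoses(pooled, minDepth = minDepth,
                                  anchors = sort(anch),
                                  refineSizes = refineSizes,
                                  idPrefix = sprintf("merge_%d", g))
    if (length(cc)) out <- c(out, cc) else out <- c(out, contigs[gi])
  }
  list(contigs = out, alleles = alleles)
}

# offset of contig j's coordinates in contig i's frame implied by an
# alignment from alignMapPair(a = contig i, b = contig j)
.pair_offset <- function(aln, ci, cj) {
  Rb <- c(0, cumsum(fragments(ci)))
  qf <- fragments(cj)
  if (aln@orientation == "-") qf <- rev(qf)
  Qb <- c(0, cumsum(qf))
  b <- aln@blocks
  qb <- c(b$qs - 1L, b$qe); rb <- c(b$rs - 1L, b$re)
  median(Rb[rb + 1L] - Qb[qb + 1L])
}

# Compose contig placements within a merge component.  An edge records the
# offset of contig j (in its aligned orientation) within contig i's frame;
# placements map a contig's own coordinate x to the root frame as
# offset + x (unflipped) or offset + span - x (flipped).
.component_placement <- function(gi, edges, contigs) {
  spans <- vapply(contigs[gi], mapSpan, numeric(1))
  root <- gi[which.max(spans)]
  placement <- list()
  placement[[as.character(root)]] <- list(offset = 0, flip = FALSE)
  place_from <- function(pKnown, spanKnown, spanNew, e, forward) {
    minus <- e$orientation == "-"
    sK <- if (pKnown$flip) -1 else 1
    A <- pKnown$offset + if (pKnown$flip) spanKnown else 0
    if (forward) {
      # x_i = e$offset + x_j ('+')  or  e$offset + span_j - x_j ('-')
      c0 <- e$offset + if (minus) spanNew else 0
    } else {
      # x_j = x_i - e$offset ('+')  or  -x_i + e$offset + span_j ('-')
      c0 <- if (minus) e$offset + spanKnown else -e$offset
    }
    val <- A + sK * c0
    flip <- xor(pKnown$flip, minus)
    list(offset = val - if (flip) spanNew else 0, flip = flip)
  }
  repeat {
    changed <- FALSE
    for (e in edges) {
      pi <- placement[[as.character(e$i)]]
      pj <- placement[[as.character(e$j)]]
      if (!is.null(pi) && is.null(pj)) {
        placement[[as.character(e$j)]] <-
          place_from(pi, mapSpan(contigs[[e$i]]), mapSpan(contigs[[e$j]]),
                     e, forward = TRUE)
        changed <- TRUE
      } else if (!is.null(pj) && is.null(pi)) {
        placement[[as.character(e$i)]] <-
          place_from(pj, mapSpan(contigs[[e$j]]), mapSpan(contigs[[e$i]]),
                     e, forward = FALSE)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  placement
}

#' Per-contig and total assembly statistics
#'
#' Mirrors the layout of a whole-genome optical map contig table: per
#' contig the span, fragment count, mean fragment size, pooled sizing SD,
#' member count and coverage, plus a Total/Ave row where averages are
#' ratios of totals, reported at 2 decimals in Mb/kb display units.
#'
#' @param contigs list of ConsensusMap.
#' @return data.frame with one row per contig plus a "Total/Ave." row.
#' @export
contigStats <- function(contigs) {
  stopifnot(length(contigs) >= 1)
  rows <- lapply(contigs, function(cm) {
    fr <- fragments(cm)
    memMass <- sum(vapply(cm@memberPoses, function(x) x$end - x$start,
                          numeric(1)))
    data.frame(contig = mapId(cm),
               spanMb = round(sum(fr) / 1e6, 2),
               nFragments = length(fr),
               meanFragKb = round(mean(fr) / 1000, 2),
               pooledSd = round(sqrt(mean(cm@spread[cm@spread > 0]^2)) / 1000,
                                2),
               nMembers = length(members(cm)),
               coverage = round(memMass / sum(fr), 2))
  })
  df <- do.call(rbind, rows)
  df$pooledSd[is.na(df$pooledSd)] <- 0
  tot <- data.frame(contig = "Total/Ave.",
                    spanMb = round(sum(df$spanMb), 2),
                    nFragments = sum(df$nFragments),
                    meanFragKb = round(sum(df$spanMb) * 1000 /
                                       sum(df$nFragments), 2),
                    pooledSd = round(sqrt(sum(df$pooledSd^2 * df$nFragments) /
                                          sum(df$nFragments)), 2),
                    nMembers = sum(df$nMembers),
                    coverage = round(sum(df$coverage * df$spanMb) /
                                     sum(df$spanMb), 2))
  rbind(df, tot)
}
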