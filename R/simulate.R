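# Synthetic-data generation: truth genomes in map space, Rmap datasets with
# the optical-map error channels, and corrupted "assemblies" with a truth
# ledger of planted discordances.
#
# The simulator operates in map space (fragment lengths); sequence emission
# exists only to exercise the in silico digestion path (simulateSequence).
# All stochastic draws flow from one seed via withSeed().

#' Simulate a truth restriction map
#'
#' Fragment lengths are drawn i.i.d. from a shifted exponential,
#' \code{500 + Exp(meanFrag - 500)}, so that the mean is exactly
#' \code{meanFrag} and no fragment is shorter than 500 bp; the last fragment
#' is trimmed so the fragments sum exactly to \code{length}.
#'
#' @param length genome length in bp (must be >= 10 x meanFrag).
#' @param meanFrag mean fragment length in bp; the default 8910 matches an
#'   average BamHI site density of one per 8.91 kb in the bovine genome.
#' @param seed RNG seed.
#' @param id map identifier.
#' @return a FragmentMap of kind "insilico" spanning exactly \code{length}.
#' @export
simulateReference <- function(length, meanFrag = 8910, seed = 1L,
                              id = "truth") {
  if (length < 10 * meanFrag) stop("length must be >= 10 x meanFrag")
  withSeed(seed, {
    floor_bp <- 500
    n_guess <- ceiling(length / meanFrag * 1.3) + 10
    frags <- numeric(0)
    total <- 0
    while (total < length) {
      draw <- floor_bp + rexp(n_guess, rate = 1 / (meanFrag - floor_bp))
      frags <- c(frags, draw)
      total <- sum(frags)
    }
    cum <- cumsum(frags)
    k <- which(cum >= length)[1]
    frags <- frags[seq_len(k)]
    frags[k] <- frags[k] - (sum(frags) - length)
    if (frags[k] < floor_bp && k > 1) {
      frags[k - 1] <- frags[k - 1] + frags[k]
      frags <- frags[-k]
    }
    frags <- round(frags)
    frags[length(frags)] <- frags[length(frags)] + (length - sum(frags))
    FragmentMap(id, frags, kind = "insilico",
                origin = list(source = "simulated", start = 0, end = length,
                              strand = "+"))
  })
}

#' Emit a nucleotide sequence realizing a truth map
#'
#' Builds a random A/C/T sequence with one BamHI site placed at each interior
#' cut of the map (sites start one bp before the cleavage coordinate so that
#' G^GATCC cleavage lands exactly on the map's cut positions).
#'
#' @param truth a FragmentMap (integer fragment lengths).
#' @param seed RNG seed.
#' @param site recognition site to plant.
#' @return a character string whose \code{digestSequence} equals \code{truth}.
#' @export
simulateSequence <- function(truth, seed = 1L, site = "GGATCC") {
  withSeed(seed, {
    len <- as.integer(mapSpan(truth))
    # base alphabet excludes G so no accidental site can form
    base <- sample(c("A", "C", "T"), len, replace = TRUE)
    cuts <- .cuts(truth)
    sitev <- strsplit(site, "")[[1]]
    for (p in cuts) {      # cleavage at p: site occupies [p-1, p+5) 0-based
      idx <- (p - 1):(p + length(sitev) - 2) + 1
      base[idx] <- sitev
    }
    paste(base, collapse = "")
  })
}

#' Simulate an Rmap dataset from a truth map
#'
#' Molecules are sheared with a truncated-normal length law and uniform
#' starts, digested site-by-site with probability \code{pDigest}, salted with
#' Poisson false cuts, perturbed with Gaussian sizing noise whose variance is
#' proportional to true fragment length, and cleaned by merging fragments
#' below the detection limit into their left neighbour.  Molecules shorter
#' than \code{minMolecule} after truncation are discarded and do not count
#' toward coverage.  Each molecule is flipped with probability 1/2 (molecule
#' orientation is unobservable on the surface).
#'
#' @param truth truth FragmentMap.
#' @param model an \linkS4class{ErrorModel}.
#' @param coverage target fold-coverage (retained molecules).
#' @param seed RNG seed.
#' @param ends "linear" truncates molecules at the truth ends (producing the
#'   molecule-end pile-ups real chromosome ends show); "interior" resamples
#'   so every molecule lies fully inside (no end pile-up; the null model for
#'   end detection).
#' @return list(rmaps = RmapSet, placements = data.frame(mapId, start, end,
#'   strand, nTrueSites, nRetainedSites, nFalseCuts)).
#' @export
simulateRmaps <- function(truth, model = errorModel(), coverage = 60,
                          seed = 1L, ends = c("linear", "interior")) {
  ends <- match.arg(ends)
  stopifnot(coverage > 0)
  if (model@pDigest == 0 && model@falseCutRate == 0)
    warning("degenerate error model: maps will have no cuts")
  L <- mapSpan(truth)
  tcuts <- .cuts(truth)
  withSeed(seed, {
    target <- coverage * L
    got <- 0
    maps <- list()
    plc <- list()
    i <- 0L
    while (got < target) {
      len <- rnorm(1, model@moleculeMean, model@moleculeSd)
      if (len < model@minMolecule / 2) next
      if (ends == "linear") {
        s <- runif(1, -len, L)
        e <- min(s + len, L)
        s <- max(s, 0)
      } else {
        if (len >= L) next
        s <- runif(1, 0, L - len)
        e <- s + len
      }
      if (e - s < model@minMolecule) next
      inside <- tcuts[tcuts > s & tcuts < e]
      keep <- if (length(inside)) as.logical(rbinom(length(inside), 1,
                                                    model@pDigest)) else logical(0)
      cuts <- inside[keep]
      nf <- rpois(1, model@falseCutRate * (e - s) / 1000)
      if (nf > 0) cuts <- sort(c(cuts, runif(nf, s, e)))
      frags <- diff(c(s, cuts, e))
      if (model@sizingVarPerBp > 0)
        frags <- frags + rnorm(length(frags),
                               sd = sqrt(model@sizingVarPerBp * frags))
      frags <- pmax(frags, 50)
      # merge sub-detectable fragments into the left neighbour
      # (the first fragment, having no left neighbour, merges right)
      if (model@minDetectable > 0) {
        repeat {
          small <- which(frags < model@minDetectable)
          if (!length(frags) || !length(small) || length(frags) == 1L) break
          k <- small[1]
          if (k == 1L) {
            frags[2] <- frags[2] + frags[1]
            frags <- frags[-1]
          } else {
            frags[k - 1L] <- frags[k - 1L] + frags[k]
            frags <- frags[-k]
          }
        }
      }
      if (sum(frags) < model@minMolecule) next  # measured span below filter
      i <- i + 1L
      id <- sprintf("rmap_%06d", i)
      strand <- if (runif(1) < 0.5) "+" else "-"
      if (strand == "-") frags <- rev(frags)
      maps[[i]] <- FragmentMap(id, frags, kind = "rmap",
                               origin = list(source = mapId(truth), start = s,
                                             end = e, strand = strand))
      plc[[i]] <- data.frame(mapId = id, start = s, end = e, strand = strand,
                             nTrueSites = length(inside),
                             nRetainedSites = sum(keep), nFalseCuts = nf)
      got <- got + (e - s)
    }
    list(rmaps = RmapSet(maps, minLengthFilter = model@minMolecule),
         placements = do.call(rbind, plc))
  })
}

.event_categories <- c("EC", "MC", "DEL", "INS", "INV", "TRANS", "COMPLEX")

#' Default planting specification
#'
#' @param nPerCategory events per category.
#' @param categories which categories to plant.
#' @param indelSize size range (bp) for DEL/INS events.
#' @param blockSize size range (bp) for INV/TRANS blocks.
#' @export
plantSpec <- function(nPerCategory = 5,
                      categories = c("EC", "MC", "DEL", "INS", "COMPLEX"),
                      indelSize = c(2e4, 6e4), blockSize = c(2e5, 1.5e6)) {
  lapply(setNames(nm = categories), function(cat) {
    size <- switch(cat,
      EC = c(0, 0), MC = c(0, 0), COMPLEX = c(0, 0),
      DEL = indelSize, INS = indelSize,
      INV = blockSize, TRANS = blockSize)
    list(n = nPerCategory, size = size)
  })
}

#' Plant assembly errors into a truth map
#'
#' Produces a corrupted copy of the truth map -- the stand-in for a sequence
#' assembly judged against the optical map -- and a truth ledger recording
#' every planted event in both coordinate systems.  Category semantics follow
#' the assembly-vs-map convention: EC adds a spurious cut to the assembly,
#' MC drops a real one, DEL adds extraneous sequence (assembly gains mass),
#' INS removes sequence (assembly loses mass), INV reverses a fragment run,
#' TRANS moves a run elsewhere, COMPLEX plants a clustered triple of cut
#' edits inside a 100 kb window.
#'
#' @param truth truth FragmentMap.
#' @param spec named list per category: list(n, size = c(min, max)); see
#'   \code{\link{plantSpec}}.
#' @param seed RNG seed.
#' @param guard minimum separation between events, bp.
#' @param structGuard minimum separation of structural events (DEL, INS,
#'   INV, TRANS) from each other and from the genome ends, bp; their
#'   flanks must be independently assemblable for the event to be
#'   interpretable (molecules that cross such an event do not align).
#' @return list(map = corrupted FragmentMap, ledger = data.frame(category,
#'   truthStart, truthEnd, asmStart, asmEnd, size, sizeDiff)).
#' @export
plantAssemblyErrors <- function(truth, spec = plantSpec(), seed = 1L,
                                guard = 5e4, structGuard = 6.5e5) {
  stopifnot(all(names(spec) %in% .event_categories))
  L <- mapSpan(truth)
  withSeed(seed, {
    # choose non-overlapping anchor intervals [pos, pos + extent) in truth bp
    events <- list()
    occupied <- matrix(numeric(0), ncol = 2)
    total_extent <- sum(vapply(spec, function(s)
      s$n * (max(s$size[2], 1e5) + 2 * guard), numeric(1)))
    if (total_extent > 0.8 * L)
      stop("infeasible planting spec: events cannot be placed disjointly")
    structCats <- c("DEL", "INS", "INV", "TRANS")
    occupiedS <- matrix(numeric(0), ncol = 2)   # structural-event envelope
    for (cat in names(spec)) {
      s <- spec[[cat]]
      if (s$n == 0) next
      isStruct <- cat %in% structCats
      g <- if (isStruct) structGuard else guard
      for (k in seq_len(s$n)) {
        size <- if (s$size[2] > 0) runif(1, s$size[1], s$size[2]) else 0
        extent <- max(size, if (cat == "COMPLEX") 1e5 else 1e4)
        placed <- FALSE
        for (try in 1:400) {
          pos <- runif(1, g, L - g - extent)
          lo <- pos - guard; hi <- pos + extent + guard
          loS <- pos - g; hiS <- pos + extent + g
          okAll <- !nrow(occupied) ||
            all(hi < occupied[, 1] | lo > occupied[, 2])
          okS <- !isStruct || !nrow(occupiedS) ||
            all(hiS < occupiedS[, 1] | loS > occupiedS[, 2])
          okS2 <- isStruct || !nrow(occupiedS) ||
            all(hi < occupiedS[, 1] | lo > occupiedS[, 2])
          if (okAll && okS && okS2) {
            occupied <- rbind(occupied, c(lo, hi))
            if (isStruct) occupiedS <- rbind(occupiedS, c(loS, hiS))
            events[[length(events) + 1L]] <-
              list(category = cat, pos = pos, size = size, extent = extent)
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("could not place all events disjointly; ",
                          "reduce counts/sizes or the guard margin")
      }
    }
    events <- events[order(vapply(events, `[[`, numeric(1), "pos"))]

    cuts <- .cuts(truth)        # operate on interior cut positions
    meanFrag <- mean(fragments(truth))
    # ledger rows in truth coordinates, with mass change per event
    led <- list()
    edits <- list()  # per event: list(removeCuts, addCuts, shiftFrom, shift)
    for (ev in events) {
      cat <- ev$category; p <- ev$pos; size <- ev$size
      near <- function(x, d = 1000) cuts[cuts > x - d & cuts < x + d]
      if (cat == "EC") {
        # extra assembly cut inside a fragment, clear of true cuts so the
        # planted site is optically resolvable
        q <- p
        for (try in 1:50) {
          if (!length(near(q, 3000))) break
          q <- q + 3100
        }
        led[[length(led) + 1L]] <- data.frame(category = "EC", truthStart = q,
          truthEnd = q, size = 0, sizeDiff = 0)
        edits[[length(edits) + 1L]] <- list(add = q, rm = numeric(0), at = q,
                                            shift = 0)
      } else if (cat == "MC") {
        # drop a cut whose flanking fragments are optically resolvable
        iv <- diff(c(0, cuts, L))
        okc <- cuts[head(iv, -1) >= 3000 & tail(iv, -1) >= 3000]
        if (!length(okc)) okc <- cuts
        q <- okc[which.min(abs(okc - p))]
        led[[length(led) + 1L]] <- data.frame(category = "MC", truthStart = q,
          truthEnd = q, size = 0, sizeDiff = 0)
        edits[[length(edits) + 1L]] <- list(add = numeric(0), rm = q, at = q,
                                            shift = 0)
      } else if (cat == "DEL") {
        # assembly gains `size` bp of extraneous sequence at p, carrying a
        # plausible density of internal sites
        ncut <- max(0, rpois(1, size / meanFrag))
        addc <- if (ncut) p + sort(runif(ncut, 0.05 * size, 0.95 * size)) else numeric(0)
        led[[length(led) + 1L]] <- data.frame(category = "DEL",
          truthStart = p, truthEnd = p, size = size, sizeDiff = size)
        edits[[length(edits) + 1L]] <- list(add = addc, rm = numeric(0),
                                            at = p, shift = size,
                                            insert = TRUE)
      } else if (cat == "INS") {
        # assembly loses the truth interval [p, p + size)
        led[[length(led) + 1L]] <- data.frame(category = "INS",
          truthStart = p, truthEnd = p + size, size = size, sizeDiff = -size)
        edits[[length(edits) + 1L]] <- list(add = numeric(0),
          rm = cuts[cuts >= p & cuts <= p + size], at = p, shift = -size,
          cutout = c(p, p + size))
      } else if (cat == "INV") {
        lo <- cuts[which.min(abs(cuts - p))]
        hi <- cuts[which.min(abs(cuts - (p + size)))]
        if (hi <= lo) next
        led[[length(led) + 1L]] <- data.frame(category = "INV",
          truthStart = lo, truthEnd = hi, size = hi - lo, sizeDiff = 0)
        edits[[length(edits) + 1L]] <- list(add = numeric(0), rm = numeric(0),
          at = lo, shift = 0, invert = c(lo, hi))
      } else if (cat == "TRANS") {
        lo <- cuts[which.min(abs(cuts - p))]
        hi <- cuts[which.min(abs(cuts - (p + size)))]
        if (hi <= lo) next
        led[[length(led) + 1L]] <- data.frame(category = "TRANS",
          truthStart = lo, truthEnd = hi, size = hi - lo, sizeDiff = 0)
        edits[[length(edits) + 1L]] <- list(add = numeric(0), rm = numeric(0),
          at = lo, shift = 0, transpose = c(lo, hi))
      } else if (cat == "COMPLEX") {
        # clustered triple of cut edits within a 100 kb window
        w0 <- p; w1 <- p + 1e5
        iv <- diff(c(0, cuts, L))
        resolvable <- cuts[head(iv, -1) >= 3000 & tail(iv, -1) >= 3000]
        inwin <- resolvable[resolvable > w0 + 5e3 & resolvable < w1 - 5e3]
        if (length(inwin) < 2) next
        rmc <- sort(sample(inwin, 2))
        for (try in 1:30) {   # edits must be separately resolvable events
          if (diff(rmc) >= 8e3) break
          rmc <- sort(sample(inwin, 2))
        }
        # place the extra cut clear of every surviving assembly cut
        left <- cuts[!(cuts %in% rmc)]
        addq <- mean(rmc)
        for (try in 1:60) {
          if (!any(abs(left - addq) < 3000)) break
          addq <- addq + 3100
        }
        led[[length(led) + 1L]] <- data.frame(category = "COMPLEX",
          truthStart = w0, truthEnd = w1, size = 1e5, sizeDiff = 0)
        edits[[length(edits) + 1L]] <- list(add = addq, rm = rmc, at = w0,
                                            shift = 0)
      }
    }
    ledger <- if (length(led)) do.call(rbind, led) else
      data.frame(category = character(0), truthStart = numeric(0),
                 truthEnd = numeric(0), size = numeric(0),
                 sizeDiff = numeric(0))

    # apply edits to the cut/position representation
    asm_cuts <- cuts
    for (e in edits) {
      if (length(e$rm)) asm_cuts <- setdiff(asm_cuts, e$rm)
      if (length(e$add)) asm_cuts <- sort(c(asm_cuts, e$add))
    }
    # structural edits (operate in truth coordinates, then shifts)
    segs <- list(list(from = 0, to = L, rev = FALSE))  # piecewise layout
    for (e in edits) {
      if (!is.null(e$invert)) {
        segs <- .split_layout(segs, e$invert[1], e$invert[2], action = "invert")
      } else if (!is.null(e$transpose)) {
        segs <- .split_layout(segs, e$transpose[1], e$transpose[2],
                              action = "transpose", L = L)
      } else if (!is.null(e$cutout)) {
        segs <- .split_layout(segs, e$cutout[1], e$cutout[2], action = "drop")
      }
    }
    # realize corrupted cut list by walking the layout
    pieces <- list()
    pos_map <- list()  # truth pos of each piece boundary for ledger asm coords
    insert_at <- vapply(edits, function(e)
      if (isTRUE(e$insert)) e$at else NA_real_, numeric(1))
    out_cuts <- numeric(0)
    offset <- 0
    isCut <- function(x) length(cuts) && min(abs(cuts - x)) < 1
    prevEndPos <- NULL
    for (sg in segs) {
      # a splice junction keeps its restriction site only when both joined
      # truth positions carried one (inversion/translocation boundaries are
      # chosen at cuts; removal junctions generally are not sites)
      startPos <- if (isTRUE(sg$rev)) sg$to else sg$from
      if (!is.null(prevEndPos) && offset > 0 &&
          isCut(prevEndPos) && isCut(startPos))
        out_cuts <- c(out_cuts, offset)
      prevEndPos <- if (isTRUE(sg$rev)) sg$from else sg$to
      inseg <- asm_cuts[asm_cuts > sg$from & asm_cuts < sg$to]
      rel <- if (sg$rev) (sg$to - rev(inseg)) else (inseg - sg$from)
      # DEL insertions inside this (forward) segment
      if (!sg$rev) {
        for (j in which(!is.na(insert_at))) {
          a <- insert_at[j]
          if (a > sg$from && a <= sg$to) {
            e <- edits[[j]]
            relins <- (e$add - sg$from)
            relcut <- a - sg$from
            rel <- sort(c(rel[rel <= relcut],
                          relins,
                          rel[rel > relcut] + e$shift))
          }
        }
      }
      extra <- 0
      for (j in which(!is.na(insert_at))) {
        a <- insert_at[j]
        if (!sg$rev && a > sg$from && a <= sg$to) extra <- extra + edits[[j]]$shift
      }
      out_cuts <- c(out_cuts, offset + rel)
      offset <- offset + (sg$to - sg$from) + extra
    }
    asmL <- offset
    out_cuts <- sort(out_cuts)
    frags <- diff(c(0, out_cuts, asmL))
    frags <- frags[frags > 1]   # guard against coincident boundaries
    corrupted <- FragmentMap(paste0(mapId(truth), "_asm"),
                             frags, kind = "insilico",
                             origin = list(source = "planted", start = 0,
                                           end = sum(frags), strand = "+"))
    # assembly coordinates: truth coordinate + net shift of earlier events
    shifts <- vapply(edits, `[[`, numeric(1), "shift")
    ats <- vapply(edits, `[[`, numeric(1), "at")
    cumshift <- function(x) sum(shifts[ats < x])
    if (!nrow(ledger)) {
      ledger$asmStart <- numeric(0); ledger$asmEnd <- numeric(0)
      ledger <- ledger[, c("category", "truthStart", "truthEnd", "asmStart",
                           "asmEnd", "size", "sizeDiff")]
      return(list(map = corrupted, ledger = ledger))
    }
    ledger$asmStart <- ledger$truthStart + vapply(ledger$truthStart, cumshift,
                                                  numeric(1))
    ledger$asmEnd <- with(ledger, ifelse(category == "INS", asmStart,
      truthEnd + vapply(truthEnd, cumshift, numeric(1))))
    isDel <- ledger$category == "DEL"
    ledger$asmEnd[isDel] <- ledger$asmStart[isDel] + ledger$size[isDel]
    ledger <- ledger[, c("category", "truthStart", "truthEnd", "asmStart",
                         "asmEnd", "size", "sizeDiff")]
    list(map = corrupted, ledger = ledger)
  })
}

# split a piecewise layout at [a, b) and apply an action to the inner run
.split_layout <- function(segs, a, b, action, L = NULL) {
  out <- list(); inner <- list()
  for (sg in segs) {
    if (sg$to <= a || sg$from >= b) { out[[length(out) + 1L]] <- sg; next }
    if (sg$from < a) out[[length(out) + 1L]] <- list(from = sg$from, to = a,
                                                     rev = sg$rev)
    inner[[length(inner) + 1L]] <- list(from = max(sg$from, a),
                                        to = min(sg$to, b), rev = sg$rev)
    if (sg$to > b) out[[length(out) + 1L]] <- list(from = b, to = sg$to,
                                                   rev = sg$rev)
  }
  if (action == "drop") return(out)
  if (action == "invert") {
    inner <- rev(lapply(inner, function(x) { x$rev <- !x$rev; x }))
    # splice inverted run back in place
    res <- list()
    spliced <- FALSE
    for (sg in out) {
      if (!spliced && sg$from >= b) { res <- c(res, inner); spliced <- TRUE }
      res[[length(res) + 1L]] <- sg
    }
    if (!spliced) res <- c(res, inner)
    return(res)
  }
  if (action == "transpose") {
    # move the run to the end of the layout (a within-map transposition)
    return(c(out, inner))
  }
  out
}
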