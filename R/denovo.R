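# Germinate-and-Grow de novo assembly: geometric quantization of fragment
# sizes, a de Bruijn graph over quantized fragment k-mers, seed-map
# germination around confident nodes, growth through the iterative engine,
# and lower-k gap-fill rounds over unassembled Rmaps.

#' Quantize a map's fragment lengths
#'
#' \code{code(f) = floor(log(f / f0) / log(1 + epsilon))}: geometric bins of
#' relative width \code{epsilon}, making codes robust to size-proportional
#' sizing error.
#'
#' @param map FragmentMap (or bare numeric fragment vector).
#' @param scheme a \linkS4class{QuantizationScheme}.
#' @return integer code per fragment.
#' @export
quantizeMap <- function(map, scheme = quantScheme()) {
  f <- if (is(map, "FragmentMap")) fragments(map) else as.numeric(map)
  stopifnot(all(f > 0))
  as.integer(floor(log(f / scheme@f0) / log(1 + scheme@epsilon)))
}

.kmer_key <- function(codes) paste(codes, collapse = ",")

# canonical form of a code window: lexicographic min of the window and its
# reversal (molecule orientation is unobservable)
.canonical <- function(codes) {
  fwd <- .kmer_key(codes); rv <- .kmer_key(rev(codes))
  if (fwd <= rv) list(key = fwd, flipped = FALSE)
  else list(key = rv, flipped = TRUE)
}

#' Build a de Bruijn graph over quantized fragment k-mers
#'
#' Every length-k window of every Rmap's code sequence increments a node
#' (canonicalized over orientation); edges connect (k-1)-overlapping windows
#' observed consecutively in a molecule.  Nodes reaching
#' \code{minMult} supporting windows are marked confident.
#'
#' @param rmaps RmapSet.
#' @param k k-mer length in fragments (default 5).
#' @param minMult confidence threshold on node multiplicity (default 5).
#' @param scheme QuantizationScheme.
#' @return list(nodes = data.frame(key, mult, confident), occurrences =
#'   per-key list of data.frame(rmap, pos), edges = data.frame(from, to,
#'   count), k, scheme).
#' @export
buildKmerGraph <- function(rmaps, k = 5, minMult = 5,
                           scheme = quantScheme(epsilon = 0.75)) {
  stopifnot(k >= 2)
  maps <- rmapList(rmaps)
  mult <- new.env(hash = TRUE, parent = emptyenv())
  occ <- new.env(hash = TRUE, parent = emptyenv())
  edge <- new.env(hash = TRUE, parent = emptyenv())
  for (m in maps) {
    codes <- quantizeMap(m, scheme)
    n <- length(codes)
    if (n < k) next
    prevKey <- NULL
    for (s in seq_len(n - k + 1L)) {
      cn <- .canonical(codes[s:(s + k - 1L)])
      key <- cn$key
      mult[[key]] <- (if (is.null(mult[[key]])) 0L else mult[[key]]) + 1L
      rec <- list(rmap = mapId(m), pos = s)
      occ[[key]] <- c(occ[[key]], list(rec))
      if (!is.null(prevKey)) {
        ek <- paste(prevKey, key, sep = "|")
        edge[[ek]] <- (if (is.null(edge[[ek]])) 0L else edge[[ek]]) + 1L
      }
      prevKey <- key
    }
  }
  keys <- ls(mult)
  mv <- vapply(keys, function(k_) mult[[k_]], integer(1))
  nodes <- data.frame(key = keys, mult = as.integer(mv),
                      confident = mv >= minMult, row.names = NULL)
  ekeys <- ls(edge)
  ef <- if (length(ekeys)) do.call(rbind, strsplit(ekeys, "|", fixed = TRUE))
        else matrix(character(0), ncol = 2)
  edges <- data.frame(from = ef[, 1], to = ef[, 2],
                      count = vapply(ekeys, function(k_) edge[[k_]],
                                     integer(1)), row.names = NULL)
  occurrences <- setNames(lapply(keys, function(k_) {
    do.call(rbind, lapply(occ[[k_]], function(r)
      data.frame(rmap = r$rmap, pos = r$pos)))
  }), keys)
  list(nodes = nodes, occurrences = occurrences, edges = edges,
       k = k, scheme = scheme)
}

#' Germinate seed maps around confident graph nodes
#'
#' Confident nodes are processed in decreasing multiplicity; for each node
#' not already consumed (more than half its supporting Rmaps assigned to an
#' earlier seed), the Rmaps containing an instance of the node are posed in
#' the frame of the node's longest member via pairwise local alignment and
#' assembled into a consensus at \code{seedMinDepth}.  Seeds extend as far
#' as their member Rmaps reach.
#'
#' @param graph result of \code{\link{buildKmerGraph}}.
#' @param rmaps the RmapSet the graph was built from.
#' @param p AlignmentParams for molecule-molecule posing; the acceptance
#'   floors are relaxed internally (molecule pairs share shorter overlaps
#'   than molecule-to-genome alignments).
#' @param seedMinDepth consensus depth for seeds (default 3; node-sharing
#'   subsets are much smaller than full piles, and \code{\link{grow}}
#'   refines seeds at the full assembly depth afterwards).
#' @param maxSeeds safety cap.
#' @return list of ConsensusMap seed maps.
#' @export
germinateSeedMaps <- function(graph, rmaps, p = alignParams(),
                              seedMinDepth = 3, maxSeeds = 500L) {
  nodes <- graph$nodes[graph$nodes$confident, , drop = FALSE]
  if (!nrow(nodes)) return(list())
  nodes <- nodes[order(-nodes$mult), , drop = FALSE]
  maps <- rmapList(rmaps)
  byid <- setNames(maps, vapply(maps, mapId, character(1)))
  posep <- alignParams(delta = p@delta, matchBonus = p@matchBonus,
                       cutPenalty = p@cutPenalty,
                       sizingVarPerBp = p@sizingVarPerBp,
                       sizingFloor = p@sizingFloor,
                       minScore = min(p@minScore, 12),
                       minAlignedFragments = min(p@minAlignedFragments, 6),
                       minScorePerFragment = 0)
  assigned <- character(0)
  seeds <- list()
  for (r in seq_len(nrow(nodes))) {
    occ <- graph$occurrences[[nodes$key[r]]]
    ids <- unique(occ$rmap)
    if (length(ids) < 2L) next
    if (mean(ids %in% assigned) > 0.5) next
    frame_id <- ids[which.max(vapply(ids, function(i)
      nFragments(byid[[i]]), integer(1)))]
    frame <- byid[[frame_id]]
    poses <- list(list(id = frame_id, start = 0, end = mapSpan(frame),
                       cuts = .cuts(frame)))
    for (id in setdiff(ids, frame_id)) {
      alns <- alignMapPair(frame, byid[[id]], posep,
                           maxAlignments = 1L)
      if (!length(alns)) next
      poses[[length(poses) + 1L]] <-
        .pose_vs_frame(byid[[id]], alns[[1]], frame)
    }
    if (length(poses) < seedMinDepth) next
    cc <- buildConsensusFromPoses(poses, minDepth = seedMinDepth,
                                  anchors = .cuts(frame),
                                  refineSizes = TRUE, relDepth = 0,
                                  idPrefix = sprintf("seed_%03d",
                                                     length(seeds) + 1L))
    if (!length(cc)) next
    seeds <- c(seeds, cc)
    assigned <- union(assigned, unlist(lapply(cc, members)))
    if (length(seeds) >= maxSeeds) break
  }
  seeds
}

# pose a molecule in a frame molecule's coordinates from a local alignment
# produced by alignMapPair(frame, molecule)
.pose_vs_frame <- function(molecule, aln, frame) {
  qf <- fragments(molecule)
  if (aln@orientation == "-") qf <- rev(qf)
  .project_pose(mapId(molecule), qf, fragments(frame), aln@blocks)
}

#' Grow seed maps with the iterative engine
#'
#' Seeds serve as the initial reference to \code{\link{iterateAssembly}},
#' which extends and refines them at full assembly depth.
#'
#' @param seeds list of seed ConsensusMaps.
#' @param rmaps RmapSet.
#' @param p AlignmentParams.
#' @param cycles iteration cycles.
#' @param minDepth consensus depth for grown contigs.
#' @param seedMinDepth depth used when consolidating overlapping seeds.
#' @param ... passed to \code{\link{iterateAssembly}}.
#' @export
grow <- function(seeds, rmaps, p = alignParams(), cycles = 8,
                 minDepth = 20, seedMinDepth = 3, ...) {
  stopifnot(length(seeds) >= 1)
  if (length(seeds) > 1L) {
    # seeds germinated from neighbouring nodes largely duplicate each
    # other; keep a low-redundancy subset so the Rmap pile is not split
    # across redundant references (contigs merge properly from cycle 2,
    # once members are posed by fitting alignments)
    ord <- order(-vapply(seeds, function(s) length(members(s)), integer(1)))
    kept <- list()
    for (s in seeds[ord]) {
      dup <- any(vapply(kept, function(k)
        length(intersect(members(s), members(k))) >
          0.5 * length(members(s)), logical(1)))
      if (!dup) kept[[length(kept) + 1L]] <- s
    }
    seeds <- kept
  }
  iterateAssembly(rmaps, seeds, cycles = cycles, p = p,
                  minDepth = minDepth, refineSizes = TRUE, ...)
}

#' Lower-k gap-fill round over unassembled Rmaps
#'
#' Reruns graph construction, germination and growth using only Rmaps not
#' represented in any prior contig, at a lower stringency (smaller k).
#'
#' @param rmaps the full RmapSet.
#' @param priorContigs contigs from earlier rounds (their members are
#'   excluded).
#' @param kSmall smaller k (default 4).
#' @param minMult,scheme graph parameters.
#' @param p,cycles,minDepth,seedMinDepth assembly parameters.
#' @return list(contigs, metrics, recruited, alleles) as from
#'   \code{\link{iterateAssembly}} (empty contig list when every Rmap is
#'   already assembled or no seed germinates).
#' @export
gapfillRound <- function(rmaps, priorContigs, kSmall = 4, minMult = 5,
                         scheme = quantScheme(epsilon = 0.75),
                         p = alignParams(),
                         cycles = 8, minDepth = 20, seedMinDepth = 3) {
  done <- unique(unlist(lapply(priorContigs, members)))
  left <- Filter(function(m) !(mapId(m) %in% done), rmapList(rmaps))
  if (!length(left))
    return(list(contigs = list(), metrics = NULL, recruited = character(0),
                alleles = data.frame()))
  sub <- RmapSet(left)
  graph <- buildKmerGraph(sub, k = kSmall, minMult = minMult, scheme = scheme)
  seeds <- germinateSeedMaps(graph, sub, p = p, seedMinDepth = seedMinDepth)
  if (!length(seeds))
    return(list(contigs = list(), metrics = NULL, recruited = character(0),
                alleles = data.frame()))
  grow(seeds, sub, p = p, cycles = cycles, minDepth = minDepth)
}
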