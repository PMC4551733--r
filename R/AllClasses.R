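#' @import methods
#' @importFrom stats median rnorm runif rbinom rpois rexp sd quantile setNames
#' @importFrom utils read.delim write.table head tail
NULL

.map_kinds <- c("rmap", "consensus", "insilico", "chromosome")

#' FragmentMap: an ordered restriction map
#'
#' The atomic data structure of optical mapping: an ordered sequence of
#' restriction fragment lengths (bp, all > 0).  A map can be a single-molecule
#' Rmap, a consensus map, an in silico digest of sequence, or a stitched
#' chromosome-wide map (the only kind allowed to carry spacer/gap fragments).
#'
#' @slot mapId single identifier string.
#' @slot enzyme restriction enzyme name, e.g. \code{"BamHI"}.
#' @slot fragments numeric vector of fragment lengths in bp, all positive.
#' @slot kind one of \code{"rmap"}, \code{"consensus"}, \code{"insilico"},
#'   \code{"chromosome"}.
#' @slot origin optional provenance list with elements \code{source},
#'   \code{start}, \code{end}, \code{strand}.
#' @slot gapFlags logical vector (length 0 or one per fragment) marking
#'   spacer/gap fragments; only \code{kind = "chromosome"} maps may have any
#'   \code{TRUE} entries.
#' @export
setClass("FragmentMap",
  slots = c(
    mapId     = "character",
    enzyme    = "character",
    fragments = "numeric",
    kind      = "character",
    origin    = "list",
    gapFlags  = "logical"
  ),
  prototype = list(enzyme = "BamHI", kind = "rmap",
                   origin = list(), gapFlags = logical(0))
)

setValidity("FragmentMap", function(object) {
  msg <- character(0)
  if (length(object@mapId) != 1L || !nzchar(object@mapId))
    msg <- c(msg, "mapId must be a single non-empty string")
  if (length(object@fragments) < 1L)
    msg <- c(msg, "a map needs at least one fragment")
  if (any(!is.finite(object@fragments)) || any(object@fragments <= 0))
    msg <- c(msg, "all fragment lengths must be finite and > 0")
  if (!object@kind %in% .map_kinds)
    msg <- c(msg, sprintf("kind must be one of %s",
                          paste(.map_kinds, collapse = ", ")))
  nf <- length(object@gapFlags)
  if (nf != 0L && nf != length(object@fragments))
    msg <- c(msg, "gapFlags must be empty or one flag per fragment")
  if (nf > 0L && any(object@gapFlags) && object@kind != "chromosome")
    msg <- c(msg, "spacer fragments are only allowed on chromosome maps")
  if (length(msg)) msg else TRUE
})

#' Construct a FragmentMap
#'
#' @param mapId identifier.
#' @param fragments numeric vector of fragment lengths (bp, > 0).
#' @param enzyme enzyme name.
#' @param kind map kind.
#' @param origin optional provenance list (source, start, end, strand).
#' @param gapFlags optional logical vector marking spacer fragments.
#' @return A \linkS4class{FragmentMap}.
#' @examples
#' fm <- FragmentMap("m1", c(11, 40, 49))
#' mapSpan(fm)
#' @export
FragmentMap <- function(mapId, fragments, enzyme = "BamHI", kind = "rmap",
                        origin = list(), gapFlags = logical(0)) {
  new("FragmentMap", mapId = as.character(mapId),
      fragments = as.numeric(fragments), enzyme = enzyme, kind = kind,
      origin = origin, gapFlags = as.logical(gapFlags))
}

#' RmapSet: a collection of single-molecule Rmaps
#'
#' @slot rmaps list of \linkS4class{FragmentMap} objects of kind "rmap".
#' @slot minLengthFilter the minimum-span filter (bp) the set satisfies.
#' @export
setClass("RmapSet",
  slots = c(rmaps = "list", minLengthFilter = "numeric"),
  prototype = list(rmaps = list(), minLengthFilter = 0)
)

setValidity("RmapSet", function(object) {
  if (!all(vapply(object@rmaps, is, logical(1), "FragmentMap")))
    return("rmaps must all be FragmentMap objects")
  ids <- vapply(object@rmaps, function(m) m@mapId, character(1))
  if (anyDuplicated(ids))
    return("duplicate map identifiers in RmapSet")
  spans <- vapply(object@rmaps, function(m) sum(m@fragments), numeric(1))
  if (length(spans) && any(spans < object@minLengthFilter))
    return("RmapSet contains maps below its minLengthFilter")
  TRUE
})

#' @rdname RmapSet-class
#' @param rmaps list of FragmentMap.
#' @param minLengthFilter minimum span (bp) the set is filtered at.
#' @export
RmapSet <- function(rmaps, minLengthFilter = 0) {
  new("RmapSet", rmaps = unname(rmaps), minLengthFilter = minLengthFilter)
}

#' ConsensusMap: an assembled optical contig
#'
#' A \linkS4class{FragmentMap} augmented with per-fragment support depth,
#' per-fragment pooled sizing spread, the identifiers of member Rmaps and
#' their posed intervals in the contig frame, an optional chromosome
#' assignment, per-end chromosome-end flags, and a tandem-repeat flag.
#'
#' @slot depth numeric, per-fragment count of supporting Rmaps.
#' @slot spread numeric, per-fragment pooled standard deviation (bp) of the
#'   member measurements (0 where fewer than two measurements exist).
#' @slot members character vector of member Rmap identifiers.
#' @slot memberPoses list of member placements in the contig frame, each a
#'   list(id, start, end, cuts).
#' @slot chromosome optional chromosome assignment.
#' @slot endFlags character of length 2 (left, right), each "interior" or
#'   "chromosome_end".
#' @slot tandemFlag logical, TRUE when the fragment pattern autocorrelation
#'   marks a long tandem repeat.
#' @export
setClass("ConsensusMap", contains = "FragmentMap",
  slots = c(
    depth       = "numeric",
    spread      = "numeric",
    members     = "character",
    memberPoses = "list",
    chromosome  = "character",
    endFlags    = "character",
    tandemFlag  = "logical"
  ),
  prototype = list(kind = "consensus", chromosome = NA_character_,
                   endFlags = c("interior", "interior"), tandemFlag = FALSE)
)

setValidity("ConsensusMap", function(object) {
  msg <- character(0)
  n <- length(object@fragments)
  if (length(object@depth) != n || length(object@spread) != n)
    msg <- c(msg, "depth and spread must have one entry per fragment")
  if (length(object@members) < 1L)
    msg <- c(msg, "a consensus map must have members")
  if (length(object@spread) && any(object@spread < 0))
    msg <- c(msg, "spread must be >= 0")
  if (length(object@endFlags) != 2L ||
      !all(object@endFlags %in% c("interior", "chromosome_end")))
    msg <- c(msg, "endFlags must be two of interior/chromosome_end")
  if (length(msg)) msg else TRUE
})

#' Alignment between two ordered restriction maps
#'
#' Blocks are colinear runs of matched fragments: block k matches query
#' fragments \code{qs..qe} against reference fragments \code{rs..re} (indices
#' in the aligned orientation of the query).  The score is the sum of the
#' per-block scores (see \code{\link{scoreBlock}}).
#'
#' @slot queryId,refId map identifiers.
#' @slot orientation "+" or "-" (query as-aligned relative to reference).
#' @slot blocks data.frame with columns qs, qe, rs, re, refLen, qryLen,
#'   dev (refLen - qryLen), score.
#' @slot score total alignment score.
#' @slot matchedSites number of matched interior cut sites.
#' @slot missedCuts,extraCuts unmatched interior sites on reference/query side.
#' @slot refStart,refEnd reference footprint in bp.
#' @export
setClass("Alignment",
  slots = c(
    queryId = "character", refId = "character", orientation = "character",
    blocks = "data.frame", score = "numeric", matchedSites = "integer",
    missedCuts = "integer", extraCuts = "integer",
    refStart = "numeric", refEnd = "numeric"
  )
)

setValidity("Alignment", function(object) {
  b <- object@blocks
  msg <- character(0)
  if (!all(c("qs", "qe", "rs", "re") %in% names(b)))
    return("blocks must have qs, qe, rs, re columns")
  if (nrow(b) > 1L) {
    if (any(diff(b$qs) <= 0) || any(diff(b$rs) <= 0))
      msg <- c(msg, "blocks must be colinear and non-overlapping")
  }
  if (!object@orientation %in% c("+", "-"))
    msg <- c(msg, "orientation must be + or -")
  if (length(msg)) msg else TRUE
})

#' Alignment scoring and acceptance parameters
#'
#' @slot delta max fragments per matched block on each side.
#' @slot matchBonus score bonus per matched block.
#' @slot cutPenalty penalty per unmatched interior site.
#' @slot sizingVarPerBp sizing-error variance per bp of reference length
#'   (bp^2/bp); the default gives SD ~ 1.3 kb on a 9 kb fragment.
#' @slot sizingFloor lower bound (bp) on the variance-scaling length.
#' @slot minScore minimum accepted alignment score.
#' @slot minAlignedFragments minimum aligned query fragments for acceptance.
#' @slot minScorePerFragment molecule-alignment quality floor: the score
#'   divided by the number of aligned query fragments must reach this value
#'   (a well-placed molecule under the error model earns ~2.1 per fragment
#'   against an in silico map; placements straddling a structural
#'   difference in the reference are systematically depressed).  Against
#'   consensus references -- themselves measured, so slightly noisier --
#'   the floor is relaxed by 0.12 internally.
#' @slot maxDevSigma molecule-alignment drift bound: an alignment is
#'   rejected when the summed deviation over any window of interior blocks
#'   (or over the whole molecule) exceeds max(8 kb, maxDevSigma x the
#'   window's sizing SD).  Keeps molecules from being stretched or
#'   compressed across real structural differences in the reference.
#' @export
setClass("AlignmentParams",
  slots = c(delta = "numeric", matchBonus = "numeric", cutPenalty = "numeric",
            sizingVarPerBp = "numeric", sizingFloor = "numeric",
            minScore = "numeric", minAlignedFragments = "numeric",
            maxDevSigma = "numeric", minScorePerFragment = "numeric"),
  prototype = list(delta = 5, matchBonus = 3, cutPenalty = 1,
                   sizingVarPerBp = 1300^2 / 9000, sizingFloor = 2000,
                   minScore = 25, minAlignedFragments = 10,
                   maxDevSigma = 4, minScorePerFragment = 1.9)
)

setValidity("AlignmentParams", function(object) {
  if (object@delta < 1) return("delta must be >= 1")
  if (object@cutPenalty < 0 || object@sizingVarPerBp <= 0)
    return("penalties must be >= 0 and sizing variance > 0")
  TRUE
})

#' @rdname AlignmentParams-class
#' @param ... slot overrides, e.g. \code{alignParams(minScore = 15)}.
#' @export
alignParams <- function(...) new("AlignmentParams", ...)

#' Rmap error model for the simulator
#'
#' @slot pDigest probability a true restriction site is cut.
#' @slot falseCutRate expected false cuts per kb.
#' @slot sizingVarPerBp variance of measured length per bp of true length
#'   (bp^2/bp); default gives SD ~ 1.3 kb at 9 kb.
#' @slot minDetectable smallest measurable fragment (bp); smaller fragments
#'   merge into the preceding fragment.
#' @slot moleculeMean,moleculeSd shearing length law (normal, bp).
#' @slot minMolecule molecules below this span (bp) are discarded.
#' @export
setClass("ErrorModel",
  slots = c(pDigest = "numeric", falseCutRate = "numeric",
            sizingVarPerBp = "numeric", minDetectable = "numeric",
            moleculeMean = "numeric", moleculeSd = "numeric",
            minMolecule = "numeric"),
  prototype = list(pDigest = 0.8, falseCutRate = 0.005,
                   sizingVarPerBp = 1300^2 / 9000, minDetectable = 800,
                   moleculeMean = 4e5, moleculeSd = 6e4, minMolecule = 3e5)
)

setValidity("ErrorModel", function(object) {
  if (object@pDigest < 0 || object@pDigest > 1)
    return("pDigest must be in [0, 1]")
  if (object@falseCutRate < 0 || object@sizingVarPerBp < 0)
    return("rates and variances must be >= 0")
  TRUE
})

#' @rdname ErrorModel-class
#' @param ... slot overrides, e.g. \code{errorModel(pDigest = 1)}.
#' @export
errorModel <- function(...) new("ErrorModel", ...)

#' Geometric fragment-size quantization scheme
#'
#' \code{code(f) = floor(log(f / f0) / log(1 + epsilon))}: relative bin width
#' \code{epsilon} around reference length \code{f0}.
#'
#' @slot epsilon relative bin width.
#' @slot f0 reference fragment length (bp).
#' @export
setClass("QuantizationScheme",
  slots = c(epsilon = "numeric", f0 = "numeric"),
  prototype = list(epsilon = 0.25, f0 = 1000))

setValidity("QuantizationScheme", function(object) {
  if (object@epsilon <= 0 || object@f0 <= 0)
    return("epsilon and f0 must be > 0")
  TRUE
})

#' @rdname QuantizationScheme-class
#' @param epsilon relative bin width.
#' @param f0 reference length (bp).
#' @export
quantScheme <- function(epsilon = 0.25, f0 = 1000)
  new("QuantizationScheme", epsilon = epsilon, f0 = f0)
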