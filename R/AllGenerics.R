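#' @describeIn FragmentMap-class map identifier
#' @param x a FragmentMap
#' @export
setGeneric("mapId", function(x) standardGeneric("mapId"))
setMethod("mapId", "FragmentMap", function(x) x@mapId)

#' @describeIn FragmentMap-class fragment lengths (bp)
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
setMethod("fragments", "FragmentMap", function(x) x@fragments)

#' @describeIn FragmentMap-class map kind
#' @export
setGeneric("mapKind", function(x) standardGeneric("mapKind"))
setMethod("mapKind", "FragmentMap", function(x) x@kind)

#' @describeIn FragmentMap-class total span, the sum of fragments (bp)
#' @export
setGeneric("mapSpan", function(x) standardGeneric("mapSpan"))
setMethod("mapSpan", "FragmentMap", function(x) sum(x@fragments))

#' @describeIn FragmentMap-class number of fragments
#' @export
setGeneric("nFragments", function(x) standardGeneric("nFragments"))
setMethod("nFragments", "FragmentMap", function(x) length(x@fragments))

#' @describeIn FragmentMap-class enzyme name
#' @export
setGeneric("enzyme", function(x) standardGeneric("enzyme"))
setMethod("enzyme", "FragmentMap", function(x) x@enzyme)

#' @describeIn FragmentMap-class spacer/gap flags (logical per fragment)
#' @export
setGeneric("gapFlags", function(x) standardGeneric("gapFlags"))
setMethod("gapFlags", "FragmentMap", function(x) {
  if (length(x@gapFlags)) x@gapFlags else rep(FALSE, length(x@fragments))
})

#' Reverse a map end-for-end
#'
#' @param x a FragmentMap
#' @return the map with fragment order (and gap flags) reversed.
#' @export
setGeneric("reverseMap", function(x) standardGeneric("reverseMap"))
setMethod("reverseMap", "FragmentMap", function(x) {
  x@fragments <- rev(x@fragments)
  if (length(x@gapFlags)) x@gapFlags <- rev(x@gapFlags)
  x
})

#' Extract a contiguous sub-map
#'
#' @param x a FragmentMap
#' @param i,j first and last fragment index (inclusive)
#' @export
setGeneric("subMap", function(x, i, j) standardGeneric("subMap"))
setMethod("subMap", "FragmentMap", function(x, i, j) {
  stopifnot(i >= 1, j <= length(x@fragments), i <= j)
  x@fragments <- x@fragments[i:j]
  if (length(x@gapFlags)) x@gapFlags <- x@gapFlags[i:j]
  x
})

#' @describeIn ConsensusMap-class per-fragment support depth
#' @param x a ConsensusMap
#' @export
setGeneric("fragmentDepth", function(x) standardGeneric("fragmentDepth"))
setMethod("fragmentDepth", "ConsensusMap", function(x) x@depth)

#' @describeIn ConsensusMap-class per-fragment pooled sizing SD (bp)
#' @export
setGeneric("fragmentSpread", function(x) standardGeneric("fragmentSpread"))
setMethod("fragmentSpread", "ConsensusMap", function(x) x@spread)

#' @describeIn ConsensusMap-class member Rmap identifiers
#' @export
setGeneric("members", function(x) standardGeneric("members"))
setMethod("members", "ConsensusMap", function(x) x@members)

setMethod("show", "FragmentMap", function(object) {
  cat(sprintf("FragmentMap '%s' [%s, %s]: %d fragments, span %.2f kb\n",
              object@mapId, object@kind, object@enzyme,
              length(object@fragments), sum(object@fragments) / 1000))
})

setMethod("show", "ConsensusMap", function(object) {
  cat(sprintf(
    "ConsensusMap '%s': %d fragments, span %.2f kb, %d members, mean depth %.1f\n",
    object@mapId, length(object@fragments), sum(object@fragments) / 1000,
    length(object@members), mean(object@depth)))
})

setMethod("show", "RmapSet", function(object) {
  spans <- vapply(object@rmaps, function(m) sum(m@fragments), numeric(1))
  cat(sprintf("RmapSet: %d Rmaps, total mass %.2f Mb (filter >= %.0f bp)\n",
              length(object@rmaps), sum(spans) / 1e6, object@minLengthFilter))
})

setMethod("show", "Alignment", function(object) {
  cat(sprintf(
    "Alignment %s -> %s (%s): score %.2f, %d blocks, ref %.1f-%.1f kb\n",
    object@queryId, object@refId, object@orientation, object@score,
    nrow(object@blocks), object@refStart / 1000, object@refEnd / 1000))
})

setMethod("length", "RmapSet", function(x) length(x@rmaps))

setMethod("[[", "RmapSet", function(x, i) x@rmaps[[i]])

#' @describeIn RmapSet-class list of member maps
#' @param x an RmapSet
#' @export
setGeneric("rmapList", function(x) standardGeneric("rmapList"))
setMethod("rmapList", "RmapSet", function(x) x@rmaps)

#' @describeIn RmapSet-class identifiers of the member maps
#' @export
setGeneric("rmapIds", function(x) standardGeneric("rmapIds"))
setMethod("rmapIds", "RmapSet", function(x)
  vapply(x@rmaps, function(m) m@mapId, character(1)))
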