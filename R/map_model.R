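# Map-dialect I/O and dataset-level statistics.
#
# OMAP dialect: TSV-ish text, one map per line
#   map_id <TAB> enzyme <TAB> f1 f2 f3 ...    (fragment lengths, bp)
# '#key=value' header lines carry file-level metadata (kind, origin);
# '#gap_flags<TAB><map_id><TAB>i,j,k' header lines mark spacer fragments
# (1-based indices); other '#' lines are comments.

.fmt_len <- function(x) {
  ifelse(abs(x - round(x)) < 1e-9, sprintf("%.0f", x), sprintf("%.2f", x))
}

#' Write maps in the OMAP dialect
#'
#' @param maps a list of \linkS4class{FragmentMap}, a single map, or an
#'   \linkS4class{RmapSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readMaps}}
#' @export
writeMaps <- function(maps, path) {
  if (is(maps, "RmapSet")) maps <- maps@rmaps
  if (is(maps, "FragmentMap")) maps <- list(maps)
  ids <- vapply(maps, mapId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate map identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  kinds <- unique(vapply(maps, mapKind, character(1)))
  if (length(kinds) == 1L) writeLines(sprintf("#kind=%s", kinds), con)
  for (m in maps) {
    gf <- m@gapFlags
    if (length(gf) && any(gf))
      writeLines(sprintf("#gap_flags\t%s\t%s", m@mapId,
                         paste(which(gf), collapse = ",")), con)
  }
  for (m in maps) {
    writeLines(paste(m@mapId, m@enzyme,
                     paste(.fmt_len(m@fragments), collapse = " "),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read maps in the OMAP dialect
#'
#' Round-trips with \code{\link{writeMaps}} bit-exactly on identifiers and
#' fragment lengths; map order is preserved.
#'
#' @param path input file.
#' @return a list of \linkS4class{FragmentMap}.
#' @export
readMaps <- function(path) {
  lines <- readLines(path)
  kind <- "rmap"
  gapinfo <- list()
  maps <- list()
  ids <- character(0)
  for (k in seq_along(lines)) {
    ln <- lines[[k]]
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      if (startsWith(ln, "#kind=")) kind <- sub("^#kind=", "", ln)
      if (startsWith(ln, "#gap_flags\t")) {
        parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        gapinfo[[parts[2]]] <- as.integer(strsplit(parts[3], ",")[[1]])
      }
      next
    }
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3L)
      stop(sprintf("malformed map line %d in '%s'", k, path))
    frags <- suppressWarnings(as.numeric(strsplit(trimws(parts[3]), "[ ]+")[[1]]))
    if (any(is.na(frags)))
      stop(sprintf("non-numeric fragment on line %d in '%s'", k, path))
    if (any(frags <= 0))
      stop(sprintf("non-positive fragment on line %d in '%s'", k, path))
    id <- parts[1]
    if (id %in% ids)
      stop(sprintf("duplicate map id '%s' on line %d", id, k))
    ids <- c(ids, id)
    gf <- logical(0)
    if (!is.null(gapinfo[[id]])) {
      gf <- rep(FALSE, length(frags))
      gf[gapinfo[[id]]] <- TRUE
    }
    maps[[length(maps) + 1L]] <- FragmentMap(id, frags, enzyme = parts[2],
                                             kind = kind, gapFlags = gf)
  }
  maps
}

#' Read an OMAP file as an RmapSet
#'
#' @param path input file.
#' @param minLengthFilter the filter the file is expected to satisfy (bp).
#' @export
readRmapSet <- function(path, minLengthFilter = 0) {
  RmapSet(readMaps(path), minLengthFilter = minLengthFilter)
}

#' Filter an RmapSet by minimum molecule span
#'
#' Retains every Rmap whose span (sum of fragment lengths) is at least
#' \code{minLen} bp; the boundary is inclusive.
#'
#' @param set an \linkS4class{RmapSet}.
#' @param minLen minimum span in bp (default 300 kb, the conventional
#'   single-molecule size cut for optical map datasets).
#' @export
filterRmaps <- function(set, minLen = 3e5) {
  stopifnot(is(set, "RmapSet"), minLen >= 0)
  spans <- vapply(set@rmaps, function(m) sum(m@fragments), numeric(1))
  RmapSet(set@rmaps[spans >= minLen], minLengthFilter = minLen)
}

#' Summary statistics of an Rmap dataset
#'
#' @param set an \linkS4class{RmapSet}.
#' @param genomeSize genome size in bp for fold-coverage; NA to skip.
#' @return one-row data.frame: nMaps, meanLengthKb, minKb, maxKb,
#'   totalMassMb, foldCoverage.  The mean is total mass / count; fold
#'   coverage is total mass / genome size, reported unrounded.
#' @export
summarizeDataset <- function(set, genomeSize = NA_real_) {
  stopifnot(is(set, "RmapSet"))
  if (length(set@rmaps) == 0L) stop("empty RmapSet")
  spans <- vapply(set@rmaps, function(m) sum(m@fragments), numeric(1))
  total <- sum(spans)
  data.frame(
    nMaps = length(spans),
    meanLengthKb = total / length(spans) / 1000,
    minKb = min(spans) / 1000,
    maxKb = max(spans) / 1000,
    totalMassMb = total / 1e6,
    foldCoverage = if (is.na(genomeSize)) NA_real_ else total / genomeSize
  )
}

# Evaluate an expression under a fixed RNG seed, restoring the caller's
# RNG state afterwards. All package-level stochastic entry points route
# their draws through this.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    set.seed(as.integer(seed))
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
  }
  force(expr)
}

# cumulative cut positions of a map: c(0, cuts..., span)
.boundaries <- function(m) c(0, cumsum(if (is(m, "FragmentMap")) m@fragments else m))

# interior cut positions (excludes the two map ends)
.cuts <- function(m) {
  b <- .boundaries(m)
  if (length(b) <= 2L) numeric(0) else b[-c(1L, length(b))]
}
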