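# In silico restriction digestion of sequence and N-gap annotation.
#
# Coordinates are 0-based half-open throughout. BamHI (GGATCC) cleaves after
# the first base of the site (G^GATCC), i.e. cleavage offset +1; since only
# inter-cut distances matter for map comparison, the offset choice is
# recorded but benign for a palindromic site.

#' Digest a nucleotide sequence in silico
#'
#' Locates exact occurrences of the recognition site on the forward strand
#' (ambiguity codes, including N, never match, so sites overlapping gap runs
#' are not called) and returns the cleavage coordinates and the fragment map.
#' Fragment lengths are the distances between consecutive cleavages plus the
#' two end pieces, so they sum exactly to the sequence length.
#'
#' @param seq a character string or \code{Biostrings::DNAString}.
#' @param site recognition pattern (default BamHI, GGATCC).
#' @param offset cut offset within the site, in bp (default 1: G^GATCC).
#' @param id identifier for the resulting map.
#' @return list(cutSites = 0-based cleavage coordinates,
#'   map = FragmentMap of kind "insilico").
#' @examples
#' d <- digestSequence(paste0(strrep("A", 10), "GGATCC", strrep("A", 30),
#'                            strrep("C", 4), "GGATCC", strrep("T", 44)))
#' fragments(d$map)  # 11 40 49
#' @export
digestSequence <- function(seq, site = "GGATCC", offset = 1, id = "seq") {
  if (!nzchar(site)) stop("recognition pattern must be non-empty")
  if (offset < 0 || offset > nchar(site)) stop("offset outside pattern")
  dna <- if (is(seq, "DNAString")) seq else Biostrings::DNAString(as.character(seq))
  len <- length(dna)
  if (len == 0L) stop("empty sequence")
  hits <- Biostrings::matchPattern(site, dna, fixed = TRUE)
  cleav <- BiocGenerics::start(hits) - 1L + offset   # 0-based cleavage coords
  cleav <- cleav[cleav > 0 & cleav < len]
  frags <- diff(c(0, cleav, len))
  list(cutSites = as.numeric(cleav),
       map = FragmentMap(id, frags, kind = "insilico",
                         origin = list(source = id, start = 0, end = len,
                                       strand = "+")))
}

#' Find assembly N-gaps in a sequence
#'
#' Maximal runs of the letter N of length >= \code{minLen}, reported as
#' 0-based half-open intervals, sorted and non-overlapping.
#'
#' @param seq character or DNAString.
#' @param minLen minimum run length in bp (default 2000, the conventional
#'   "large gap" cut).
#' @param name sequence name for the output.
#' @return data.frame(name, start, end, length).
#' @export
findSequenceGaps <- function(seq, minLen = 2000, name = "seq") {
  stopifnot(minLen >= 1)
  s <- as.character(seq)
  m <- gregexpr("N+", s)[[1]]
  if (m[1] == -1L)
    return(data.frame(name = character(0), start = numeric(0),
                      end = numeric(0), length = numeric(0)))
  st <- as.numeric(m) - 1
  ln <- as.numeric(attr(m, "match.length"))
  keep <- ln >= minLen
  data.frame(name = rep(name, sum(keep)), start = st[keep],
             end = st[keep] + ln[keep], length = ln[keep])
}

#' Digest every record of a FASTA file
#'
#' @param fasta path to a (possibly gzipped) FASTA file, or a named
#'   \code{DNAStringSet}.
#' @param site,offset as in \code{\link{digestSequence}}.
#' @param gapMinLen minimum N-run length annotated per record.
#' @return named list per record: list(map, cutSites, gaps).
#' @export
digestGenome <- function(fasta, site = "GGATCC", offset = 1, gapMinLen = 2000) {
  seqs <- if (is(fasta, "DNAStringSet")) fasta
          else Biostrings::readDNAStringSet(fasta)
  nms <- names(seqs)
  if (is.null(nms) || any(!nzchar(nms))) stop("FASTA records must be named")
  nms <- sub("\\s.*$", "", nms)
  if (anyDuplicated(nms))
    stop("duplicate record names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  out <- vector("list", length(seqs))
  names(out) <- nms
  for (i in seq_along(seqs)) {
    d <- digestSequence(seqs[[i]], site = site, offset = offset, id = nms[i])
    g <- findSequenceGaps(seqs[[i]], minLen = gapMinLen, name = nms[i])
    out[[i]] <- list(map = d$map, cutSites = d$cutSites, gaps = g)
  }
  out
}

#' Write N-gap intervals as 3-column BED
#'
#' @param gaps data.frame from \code{\link{findSequenceGaps}} (possibly
#'   row-bound across records).
#' @param path output file.
#' @export
writeGapsBed <- function(gaps, path) {
  write.table(gaps[, c("name", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
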