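# End-to-end orchestration (simulate -> assemble -> stitch -> audit),
# truth-ledger scoring, and recomputation of the packaged in-paper tables.

#' Load a packaged fixture table
#'
#' Packaged transcriptions of the published bovine optical map summary
#' tables: "table1_contigs" (78 contig rows), "table2_segments"
#' (per-chromosome alignment segments), "table3_discordances",
#' "dataset_summary" (Rmap dataset totals) and "discussion_tallies"
#' (gap/discordance counts).
#'
#' @param name fixture name (without extension).
#' @return data.frame.
#' @export
omtkFixture <- function(name = c("table1_contigs", "table2_segments",
                                 "table3_discordances", "dataset_summary",
                                 "discussion_tallies")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "omtk")
  if (!nzchar(path)) stop("fixture not found: ", name)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Recompute the in-paper tables from their row-level fixtures
#'
#' Every derived value (totals, means, percentages) is recomputed from the
#' transcribed row-level data and compared with the printed value at its
#' printed precision.  Two printed Btau4.6 percentages disagree with their
#' own counts on recomputation; they are flagged, not silently corrected.
#'
#' @return data.frame(table, quantity, recomputed, printed, agrees).
#' @export
reproducePaperTables <- function() {
  t1 <- omtkFixture("table1_contigs")
  t2 <- omtkFixture("table2_segments")
  ds <- omtkFixture("dataset_summary")
  dt <- omtkFixture("discussion_tallies")
  rows <- list()
  addrow <- function(tab, q, rec, pr, tol = 0.005 * abs(pr)) {
    rows[[length(rows) + 1L]] <<- data.frame(table = tab, quantity = q,
      recomputed = rec, printed = pr, agrees = abs(rec - pr) <= tol)
  }
  totalSpan <- sum(t1$size_mb)
  totalFrags <- sum(t1$n_fragments)
  addrow("Table1", "total_span_mb", round(totalSpan, 2), 2575.30, 0.05)
  addrow("Table1", "mean_contig_mb", round(totalSpan / nrow(t1), 2), 33.02,
         0.01)
  addrow("Table1", "mean_fragment_kb",
         round(totalSpan * 1000 / totalFrags, 2), 8.91, 0.01)
  addrow("Table1", "n_fragments", totalFrags, 289156, 0)
  addrow("Table1", "n_contigs", nrow(t1), 78, 0)
  addrow("Table1", "n_rmaps", sum(t1$n_rmaps), 567886, 0)

  addrow("Table2", "umd_n_segments", sum(t2$n_seg_umd), 135, 0)
  addrow("Table2", "btau_n_segments", sum(t2$n_seg_btau), 188, 0)
  addrow("Table2", "umd_mean_segment_mb",
         round(sum(t2$mass_umd_mb) / sum(t2$n_seg_umd), 2), 17.02, 0.01)
  addrow("Table2", "btau_mean_segment_mb",
         round(sum(t2$mass_btau_mb) / sum(t2$n_seg_btau), 2), 10.93, 0.01)
  addrow("Table2", "umd_total_mass_mb", round(sum(t2$mass_umd_mb), 2),
         2297.08, 0.05)
  addrow("Table2", "btau_total_mass_mb", round(sum(t2$mass_btau_mb), 2),
         2054.74, 0.05)
  addrow("Table2", "umd_pct_coverage",
         round(100 * sum(t2$mass_umd_mb) / sum(t2$chr_size_umd_mb), 2),
         86.33, 0.01)
  addrow("Table2", "btau_pct_coverage",
         round(100 * sum(t2$mass_btau_mb) / sum(t2$chr_size_btau_mb), 2),
         78.13, 0.01)

  addrow("Dataset", "mean_rmap_kb",
         round(ds$total_mass_mb * 1000 / ds$n_rmaps, 2), 397.49, 0.01)
  addrow("Dataset", "fold_coverage",
         round(ds$total_mass_mb / ds$genome_size_mb, 0), 270, 1)

  u <- dt[dt$build == "UMD3.1", ]; b <- dt[dt$build == "Btau4.6", ]
  addrow("Discussion", "umd_pct_gaps_intersected",
         round(100 * u$n_gaps_intersected / u$n_gaps_ge2kb, 1),
         u$printed_gap_pct, 0.05)
  addrow("Discussion", "umd_pct_disc_intersecting",
         round(100 * u$n_disc_intersecting / u$n_discordances, 1),
         u$printed_disc_pct, 0.05)
  addrow("Discussion", "umd_pct_gaps_bridged",
         round(100 * u$n_gaps_bridged / u$n_gaps_ge2kb, 1), 96.4, 0.05)
  addrow("Discussion", "btau_pct_gaps_bridged",
         round(100 * b$n_gaps_bridged / b$n_gaps_ge2kb, 1), 99.1, 0.05)
  # two printed Btau4.6 percentages do not match their own counts
  addrow("Discussion", "btau_pct_gaps_intersected",
         round(100 * b$n_gaps_intersected / b$n_gaps_ge2kb, 1),
         b$printed_gap_pct, 0.05)
  addrow("Discussion", "btau_pct_disc_intersecting",
         round(100 * b$n_disc_intersecting / b$n_discordances, 1),
         b$printed_disc_pct, 0.05)
  do.call(rbind, rows)
}

#' Score called discordances against a truth ledger
#'
#' A planted event is recovered when a call overlaps its corrupted-assembly
#' interval within \code{tol}; the category is correct when the call's
#' category matches (INV/TRANS plants match IT calls of the corresponding
#' subtype).
#'
#' @param disc discordance calls (sequence coordinates = corrupted build).
#' @param ledger truth ledger from \code{\link{plantAssemblyErrors}}.
#' @param tol matching tolerance bp (default 5 kb).
#' @return list(recall, categoryAccuracy, precision, perEvent).
#' @export
scoreAgainstLedger <- function(disc, ledger, tol = 5e3) {
  catmap <- function(cat) if (cat %in% c("INV", "TRANS")) "IT" else cat
  matched <- logical(nrow(ledger))
  correct <- logical(nrow(ledger))
  usedCall <- rep(FALSE, nrow(disc))
  for (k in seq_len(nrow(ledger))) {
    lo <- ledger$asmStart[k] - tol; hi <- ledger$asmEnd[k] + tol
    hit <- which(disc$seqStart <= hi & disc$seqEnd >= lo)
    if (!length(hit)) next
    matched[k] <- TRUE
    usedCall[hit] <- TRUE
    want <- catmap(ledger$category[k])
    correct[k] <- want %in% disc$category[hit]
  }
  list(recall = mean(matched),
       categoryAccuracy = if (any(matched)) mean(correct[matched]) else NA,
       precision = if (nrow(disc)) mean(usedCall) else NA,
       perEvent = data.frame(category = ledger$category, matched = matched,
                             correct = correct))
}

#' Default pipeline configuration
#'
#' Desk-scale study conditions: a 20 Mb truth genome at 60-fold Rmap
#' coverage with the default error model, five planted events per
#' discordance category on the seeding "assembly", eight assembly cycles at
#' minimum depth 20.
#'
#' @param length truth genome length bp.
#' @param coverage Rmap fold coverage.
#' @param seed master seed; all stage seeds derive from it.
#' @param ... overrides for any config entry.
#' @export
pipelineConfig <- function(length = 2e7, coverage = 60, seed = 1L, ...) {
  cfg <- list(
    length = length, coverage = coverage, seed = as.integer(seed),
    model = errorModel(), params = alignParams(),
    plant = plantSpec(), plantGuard = 1e5,
    cycles = 8, minDepth = 20, binSize = 1e6, overlap = 5e5,
    denovo = TRUE, kmerK = 5, kmerMinMult = 5, gapfillK = 4,
    stages = c("simulate", "assemble", "denovo", "stitch", "discord"),
    outDir = NULL)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Run the full pipeline on simulated data
#'
#' Simulates a truth genome, a corrupted "sequence assembly" with a ledger
#' of planted discordances, and an Rmap dataset; runs iterative assembly
#' seeded by the corrupted assembly, routes unrecruited Rmaps to
#' Germinate-and-Grow, merges, orders/orients and stitches chromosome-wide
#' maps, extracts map segments, calls discordances and ITs, and scores the
#' calls against the ledger.  Deterministic for a fixed seed.
#'
#' @param config from \code{\link{pipelineConfig}}.
#' @return list with elements truth, build, ledger, rmaps, assembly,
#'   denovo, contigs, placements, chromosome, segments, endExtension,
#'   discordances, its, ledgerScore, contigStats, datasetSummary.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  seed <- config$seed
  stages <- config$stages
  res <- list(config = config)

  truth <- simulateReference(config$length, seed = seed)
  planted <- plantAssemblyErrors(truth, spec = config$plant,
                                 seed = seed + 1L, guard = config$plantGuard)
  build <- planted$map
  res$truth <- truth; res$build <- build; res$ledger <- planted$ledger
  sim <- simulateRmaps(truth, model = config$model,
                       coverage = config$coverage, seed = seed + 2L)
  res$rmaps <- sim$rmaps; res$placements <- sim$placements
  res$datasetSummary <- summarizeDataset(sim$rmaps, genomeSize = config$length)
  if (!("assemble" %in% stages)) return(res)

  asm <- iterateAssembly(sim$rmaps, build, cycles = config$cycles,
                         p = config$params, minDepth = config$minDepth,
                         binSize = config$binSize, overlap = config$overlap)
  res$assembly <- asm
  contigs <- asm$contigs

  if (config$denovo && "denovo" %in% stages) {
    gf <- gapfillRound(sim$rmaps, contigs, kSmall = config$gapfillK,
                       minMult = config$kmerMinMult, p = config$params,
                       cycles = config$cycles, minDepth = config$minDepth)
    res$denovo <- gf
    if (length(gf$contigs)) {
      merged <- mergeContigs(c(contigs, gf$contigs), p = config$params,
                             minDepth = config$minDepth)
      contigs <- merged$contigs
    }
  }
  for (k in seq_along(contigs))
    contigs[[k]]@mapId <- sprintf("contig_%03d", k)
  res$contigs <- contigs
  if (length(contigs)) res$contigStats <- contigStats(contigs)
  if (!("stitch" %in% stages) || !length(contigs)) return(res)

  buildMaps <- list(chr1 = build)
  plc <- orderAndOrient(contigs, buildMaps, p = config$params)
  res$contigPlacements <- plc
  if (!nrow(plc)) return(res)
  st <- stitchChromosome(plc, contigs, chrom = "chr1", onOverlap = "trim")
  res$chromosome <- st
  seg <- extractMapSegments(st$map, build, p = config$params,
                            chrom = "chr1")
  res$segments <- seg$segments; res$segmentStats <- seg$stats
  res$endExtension <- endExtension(st$map, build, seg$segments)
  if (!("discord" %in% stages)) return(res)

  disc <- callDiscordances(st$map, build, p = config$params, chrom = "chr1",
                           optDepth = st$depth, junctions = st$junctions)
  its <- callITs(list(chr1_OM = st$map), list(chr1 = build),
                 p = config$params)
  res$discordances <- disc; res$its <- its
  allcalls <- disc
  if (nrow(its))
    allcalls <- rbind(disc, its[, names(disc), drop = FALSE])
  res$ledgerScore <- scoreAgainstLedger(allcalls, planted$ledger)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    writeMaps(truth, file.path(config$outDir, "truth.omap"))
    writeMaps(build, file.path(config$outDir, "build.omap"))
    writeMaps(sim$rmaps, file.path(config$outDir, "rmaps.omap"))
    if (length(contigs))
      writeMaps(contigs, file.path(config$outDir, "contigs.omap"))
    writeMaps(st$map, file.path(config$outDir, "chromosome.omap"))
    write.table(sim$placements, file.path(config$outDir, "placements.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(planted$ledger, file.path(config$outDir, "ledger.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$segments, file.path(config$outDir, "segments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$contigStats))
      write.table(res$contigStats, file.path(config$outDir,
                                             "contig_stats.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    exportDiscordances(allcalls, file.path(config$outDir,
                                           "discordances.tsv"))
  }
  res
}
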