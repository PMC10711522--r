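.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full reference-library validation pipeline
#'
#' Executes distances -> barcode-gap records -> rank summaries -> trees
#' (NJ metric, UPGMA ultrametric unless supplied) -> four delimitations
#' (SLC, ASAP, PTP, GMYC) -> majority-rule consensus -> conflict report
#' -> accumulation curves, and optionally writes every table plus a
#' machine-readable run manifest. Any stage error aborts with the stage
#' name. All randomness derives from \code{seed}.
#'
#' @param library A [ReferenceLibrary-class].
#' @param outDir Output directory (created); \code{NULL} to skip writing.
#' @param seed Integer root seed.
#' @param slcThreshold Single-linkage threshold (default 0.022).
#' @param majority Consensus majority fraction.
#' @param includeMorphology Let morphological species labels vote in the
#'   consensus (a flag excludes them for a strictly molecular consensus).
#' @param ptpMode,gmycMode Rate modes passed to [ptpFit()] / [gmycFit()].
#' @param metricTree,ultrametricTree Optional user-supplied \code{phylo}
#'   trees; defaults are built from the K2P matrix (NJ / UPGMA).
#' @param nPermutations Accumulation-curve permutations.
#' @return List bundle: \code{distances}, \code{gapTable},
#'   \code{rankSummaries}, \code{njTree}, \code{upgmaTree},
#'   \code{partitions}, \code{models}, \code{consensus}, \code{conflict},
#'   \code{accumulation} (species- and MOTU-level), \code{manifest}.
#' @export
runPipeline <- function(library, outDir = NULL, seed = 1,
                        slcThreshold = 0.022, majority = 0.5,
                        includeMorphology = TRUE,
                        ptpMode = "single", gmycMode = "single",
                        metricTree = NULL, ultrametricTree = NULL,
                        nPermutations = 100) {
  species <- speciesLabels(library)
  d <- .stage("distances", k2pMatrix(library))
  gapTable <- .stage("gap_records", speciesGapTable(d, species))
  ranks <- .stage("rank_summaries",
                  rankSummaries(d, libraryMetadata(library)))
  nj <- .stage("nj_tree",
               if (is.null(metricTree)) njTree(d) else metricTree)
  up <- .stage("upgma_tree",
               if (is.null(ultrametricTree)) upgmaTree(d)
               else ultrametricTree)
  slc <- .stage("slc", slcCluster(d, threshold = slcThreshold))
  asap <- .stage("asap", asapPartitions(d))
  ptp <- .stage("ptp", ptpFit(nj, mode = ptpMode, seed = seed + 1L))
  gmyc <- .stage("gmyc", gmycFit(up, mode = gmycMode, seed = seed + 2L))
  partitions <- list(slc, asap@best, ptp@partition, gmyc@partition)
  voters <- partitions
  if (includeMorphology) {
    lab <- !is.na(species)
    if (all(lab))
      voters <- c(voters, list(motuPartition("MORPHOLOGY", species)))
    else if (any(lab))
      warning("morphology vote skipped: ", sum(!lab),
              " unidentified record(s)")
  }
  consensus <- .stage("consensus", consensusPartition(voters, m = majority))
  conflict <- .stage("conflict_report",
                     conflictReport(consensus, species, gapTable))
  accSpecies <- .stage("accumulation_species",
                       accumulationCurve(unname(species)[!is.na(species)],
                                         nPermutations = nPermutations,
                                         seed = seed + 3L))
  accMotu <- .stage("accumulation_motu",
                    accumulationCurve(
                      unname(motuAssignments(consensus@partition)),
                      nPermutations = nPermutations, seed = seed + 4L))
  manifest <- list(
    package_version = as.character(utils::packageVersion("motuforge")),
    n_sequences = length(seqIds(library)),
    alignment_length = alignmentLength(library),
    n_species = length(unique(stats::na.omit(species))),
    seed = seed,
    parameters = list(slc_threshold = slcThreshold, majority = majority,
                      include_morphology = includeMorphology,
                      ptp_mode = ptpMode, gmyc_mode = gmycMode,
                      n_permutations = nPermutations),
    motu_counts = c(SLC = motuCount(slc), ASAP = motuCount(asap@best),
                    PTP = motuCount(ptp@partition),
                    GMYC = motuCount(gmyc@partition),
                    CONSENSUS = motuCount(consensus@partition)),
    n_undefined_distances = attr(d, "n_undefined"),
    conflict_summary = as.list(conflict$summary))
  bundle <- list(distances = d, gapTable = gapTable,
                 rankSummaries = ranks, njTree = nj, upgmaTree = up,
                 partitions = c(partitions,
                                list(consensus@partition)),
                 models = list(asap = asap, ptp = ptp, gmyc = gmyc),
                 consensus = consensus, conflict = conflict,
                 accumulation = list(species = accSpecies,
                                     motu = accMotu),
                 manifest = manifest)
  if (!is.null(outDir)) .writeBundle(bundle, library, outDir)
  bundle
}

.writeBundle <- function(bundle, library, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(outDir, f), sep = "\t", quote = FALSE,
    row.names = FALSE, na = "")
  tsv(distanceTable(bundle$distances), "distances.tsv")
  gp <- bundle$gapTable
  gp[c("max_intra", "nn_dist", "fold")] <-
    lapply(gp[c("max_intra", "nn_dist", "fold")], round, 4)
  tsv(gp, "gap_records.tsv")
  rs <- bundle$rankSummaries
  rs[c("min", "mean", "max", "se")] <-
    lapply(rs[c("min", "mean", "max", "se")], round, 4)
  tsv(rs, "rank_summaries.tsv")
  writePartitionTable(bundle$partitions,
                      file.path(outDir, "partitions.tsv"))
  tsv(bundle$conflict$classification, "conflict_report.tsv")
  tsv(bundle$accumulation$species, "accumulation_species.tsv")
  tsv(bundle$accumulation$motu, "accumulation_motu.tsv")
  ape::write.tree(bundle$njTree, file.path(outDir, "nj.nwk"))
  ape::write.tree(bundle$upgmaTree, file.path(outDir, "upgma.nwk"))
  jsonlite::write_json(bundle$manifest,
                       file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

#' Taxonomic coverage table
#'
#' Per-order counts of families, genera, species and sequences; missing
#' rank values are counted as \code{"unassigned"}. An optional checklist
#' (columns \code{order, families, genera, species}) adds the
#' checklist/observed columns and the percentage of checklist species
#' represented.
#'
#' @param library A [ReferenceLibrary-class].
#' @param checklist Optional reference checklist data.frame.
#' @return data.frame, one row per order plus a \code{Total} row.
#' @export
summarizeCounts <- function(library, checklist = NULL) {
  md <- libraryMetadata(library)
  if (!nrow(md))
    return(data.frame(order = character(0), families = integer(0),
                      genera = integer(0), species = integer(0),
                      sequences = integer(0)))
  for (cc in c("order", "family", "genus", "species"))
    md[[cc]][is.na(md[[cc]])] <- "unassigned"
  cnt <- function(v) length(unique(v))
  agg <- do.call(rbind, lapply(split(md, md$order), function(g)
    data.frame(order = g$order[1], families = cnt(g$family),
               genera = cnt(g$genus), species = cnt(g$species),
               sequences = nrow(g), stringsAsFactors = FALSE)))
  agg <- agg[order(agg$order), , drop = FALSE]
  total <- data.frame(order = "Total", families = cnt(md$family),
                      genera = cnt(md$genus), species = cnt(md$species),
                      sequences = nrow(md), stringsAsFactors = FALSE)
  out <- rbind(agg, total)
  rownames(out) <- NULL
  if (!is.null(checklist)) {
    i <- match(out$order, checklist$order)
    out$checklist_species <- checklist$species[i]
    out$percent_represented <-
      round(100 * out$species / out$checklist_species, 1)
  }
  out
}
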