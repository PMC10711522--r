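#' Read an aligned FASTA plus metadata table into a ReferenceLibrary
#'
#' The metadata file is a tab-separated UTF-8 table with a header row and
#' columns \code{sequence_id, species, genus, family, order, source, site}.
#' Unknown species are encoded as empty fields and become \code{NA}
#' (excluded from species-level statistics, retained for delimitation).
#' FASTA records without a metadata row are rejected with a warning.
#'
#' @param fastaPath Path to the aligned FASTA (single-line or wrapped).
#' @param metadataPath Path to the tab-separated metadata table.
#' @return A validated [ReferenceLibrary-class].
#' @export
readLibrary <- function(fastaPath, metadataPath) {
  seqs <- Biostrings::readDNAStringSet(fastaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  md <- utils::read.delim(metadataPath, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  referenceLibrary(seqs, md)
}

#' Write a ReferenceLibrary to FASTA + metadata TSV
#'
#' @param library A [ReferenceLibrary-class].
#' @param fastaPath,metadataPath Output paths.
#' @return Invisibly, the two paths.
#' @export
writeLibrary <- function(library, fastaPath, metadataPath) {
  Biostrings::writeXStringSet(library@sequences, fastaPath)
  utils::write.table(library@metadata, metadataPath, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "",
                     fileEncoding = "UTF-8")
  invisible(c(fastaPath, metadataPath))
}

#' Screen sequences for stop codons under the vertebrate mitochondrial code
#'
#' Each sequence is stripped of alignment gaps and translated in all three
#' forward frames; the frame with the fewest stop codons is retained.
#' Protein-coding barcodes (COI) should show zero stops in at least one
#' frame; a positive minimum flags a likely pseudogene or sequencing
#' artefact. Ambiguous codons translate to \code{X} and never count as
#' stops. Sequences with fewer than three ungapped bases are reported as
#' untranslatable (and flagged).
#'
#' @param library A [ReferenceLibrary-class].
#' @param geneticCode A genetic code as returned by
#'   [Biostrings::getGeneticCode()]; defaults to the vertebrate
#'   mitochondrial code (id "2"), under which TAA, TAG, AGA and AGG are
#'   stops.
#' @return data.frame with one row per sequence: \code{sequence_id},
#'   \code{min_stops}, \code{frame} (1-3, frame attaining the minimum),
#'   \code{flagged}, \code{untranslatable}.
#' @export
checkStopCodons <- function(library,
                            geneticCode = Biostrings::getGeneticCode("2")) {
  ids <- seqIds(library)
  chr <- as.character(library@sequences)
  res <- lapply(chr, function(s) {
    s <- gsub("[-.]", "", s)
    n <- nchar(s)
    if (n < 3L)
      return(list(min_stops = NA_integer_, frame = NA_integer_,
                  flagged = TRUE, untranslatable = TRUE))
    stops <- vapply(1:3, function(f) {
      len <- n - f + 1L
      len <- len - (len %% 3L)
      if (len < 3L) return(NA_integer_)
      aa <- Biostrings::translate(
        Biostrings::DNAString(substr(s, f, f + len - 1L)),
        genetic.code = geneticCode, if.fuzzy.codon = "X")
      Biostrings::countPattern("*", aa)
    }, integer(1))
    if (all(is.na(stops)))
      return(list(min_stops = NA_integer_, frame = NA_integer_,
                  flagged = TRUE, untranslatable = TRUE))
    f <- which.min(stops)
    list(min_stops = stops[f], frame = as.integer(f),
         flagged = stops[f] > 0L, untranslatable = FALSE)
  })
  data.frame(sequence_id = ids,
             min_stops = vapply(res, `[[`, integer(1), "min_stops"),
             frame = vapply(res, `[[`, integer(1), "frame"),
             flagged = vapply(res, `[[`, logical(1), "flagged"),
             untranslatable = vapply(res, `[[`, logical(1),
                                     "untranslatable"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write / read a partition table
#'
#' The table has one row per sequence and one column per delimitation
#' scheme; re-reading reproduces the partitions exactly. All partitions
#' must cover the same sequence id set.
#'
#' @param partitions A list of [MotuPartition-class] objects (names are
#'   ignored; column names come from each partition's method, made unique).
#' @param path Output TSV path.
#' @return Invisibly, the written data.frame.
#' @export
writePartitionTable <- function(partitions, path) {
  df <- partitionTable(partitions)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(df)
}

#' @describeIn writePartitionTable Assemble the table without writing it.
#' @export
partitionTable <- function(partitions) {
  if (!length(partitions)) stop("empty partition list")
  if (!all(vapply(partitions, methods::is, logical(1), "MotuPartition")))
    stop("all elements must be MotuPartition objects")
  ids <- names(partitions[[1]]@assignment)
  for (p in partitions[-1])
    if (!setequal(names(p@assignment), ids))
      stop("partitions cover different sequence id sets")
  df <- data.frame(sequence_id = ids, stringsAsFactors = FALSE)
  cols <- make.unique(vapply(partitions, motuMethod, character(1)))
  for (i in seq_along(partitions))
    df[[cols[i]]] <- unname(partitions[[i]]@assignment[ids])
  df
}

#' @describeIn writePartitionTable Read a partition table back into a list
#'   of \code{MotuPartition} objects (one per non-id column).
#' @export
readPartitionTable <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  if (!"sequence_id" %in% colnames(df))
    stop("partition table lacks a sequence_id column")
  cols <- setdiff(colnames(df), "sequence_id")
  stats::setNames(lapply(cols, function(cc)
    motuPartition(cc, stats::setNames(df[[cc]], df$sequence_id))), cols)
}
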