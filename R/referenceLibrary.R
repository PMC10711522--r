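#' Construct a ReferenceLibrary
#'
#' @param sequences A named [Biostrings::DNAStringSet] (or named character
#'   vector) of aligned sequences, equal widths.
#' @param metadata data.frame with columns \code{sequence_id, species,
#'   genus, family, order, source, site}. Rows are matched to sequences by
#'   \code{sequence_id}; empty species strings become \code{NA}
#'   (unidentified records).
#' @return A validated [ReferenceLibrary-class].
#' @examples
#' seqs <- c(a = "ACGT", b = "ACGA")
#' md <- data.frame(sequence_id = c("a", "b"), species = "Sp1",
#'                  genus = "G1", family = "F1", order = "O1",
#'                  source = "trawl", site = "s1")
#' lib <- referenceLibrary(seqs, md)
#' @export
referenceLibrary <- function(sequences, metadata) {
  if (!methods::is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(sequences)
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  missingCols <- setdiff(.metadataCols, colnames(metadata))
  if (length(missingCols))
    stop("metadata lacks columns: ", paste(missingCols, collapse = ", "))
  for (cc in .metadataCols) {
    metadata[[cc]] <- as.character(metadata[[cc]])
    metadata[[cc]][!is.na(metadata[[cc]]) &
                   trimws(metadata[[cc]]) == ""] <- NA_character_
  }
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named")
  if (anyDuplicated(metadata$sequence_id))
    stop("duplicate sequence_id in metadata: ",
         paste(unique(metadata$sequence_id[duplicated(metadata$sequence_id)]),
               collapse = ", "))
  noMeta <- setdiff(ids, metadata$sequence_id)
  if (length(noMeta)) {
    warning(length(noMeta), " sequence(s) without a metadata row rejected: ",
            paste(utils::head(noMeta, 5), collapse = ", "))
    sequences <- sequences[setdiff(ids, noMeta)]
    ids <- names(sequences)
  }
  if (length(sequences) == 0L) stop("no sequences with metadata remain")
  metadata <- metadata[match(ids, metadata$sequence_id), , drop = FALSE]
  rownames(metadata) <- NULL
  methods::new("ReferenceLibrary", sequences = sequences, metadata = metadata)
}

#' @describeIn referenceLibrary Sequence ids, in library order.
#' @param x,object A \code{ReferenceLibrary}.
#' @export
seqIds <- function(x) names(x@sequences)

#' @describeIn referenceLibrary Alignment length (bp).
#' @export
alignmentLength <- function(x) unique(Biostrings::width(x@sequences))[1]

#' @describeIn referenceLibrary The aligned sequences as a
#'   \code{DNAStringSet}.
#' @export
librarySequences <- function(x) x@sequences

#' @describeIn referenceLibrary The specimen metadata table.
#' @export
libraryMetadata <- function(x) x@metadata

#' @describeIn referenceLibrary Named vector of species labels
#'   (\code{NA} = unidentified).
#' @export
speciesLabels <- function(x)
  stats::setNames(x@metadata$species, x@metadata$sequence_id)

#' Subset a reference library by sequence id
#'
#' @param x A \code{ReferenceLibrary}.
#' @param ids Character vector of sequence ids to keep (order preserved
#'   as given).
#' @return A \code{ReferenceLibrary} restricted to \code{ids}.
#' @export
subsetLibrary <- function(x, ids) {
  stopifnot(all(ids %in% seqIds(x)))
  referenceLibrary(x@sequences[ids],
                   x@metadata[match(ids, x@metadata$sequence_id), ,
                              drop = FALSE])
}

setMethod("show", "ReferenceLibrary", function(object) {
  md <- object@metadata
  cat(sprintf("ReferenceLibrary: %d sequences x %d bp\n",
              length(object@sequences), alignmentLength(object)))
  cat(sprintf("  species: %d (%d unidentified records), genera: %d, families: %d, orders: %d\n",
              length(unique(stats::na.omit(md$species))), sum(is.na(md$species)),
              length(unique(stats::na.omit(md$genus))),
              length(unique(stats::na.omit(md$family))),
              length(unique(stats::na.omit(md$order)))))
  src <- table(md$source, useNA = "ifany")
  cat("  source:", paste(sprintf("%s=%d", names(src), src), collapse = ", "),
      "\n")
})

#' Construct a MotuPartition
#'
#' @param method Producing method label (e.g. \code{"SLC"}).
#' @param assignment Named character (or factor/integer) vector mapping
#'   every sequence id to a MOTU label.
#' @return A validated [MotuPartition-class].
#' @export
motuPartition <- function(method, assignment) {
  a <- stats::setNames(as.character(assignment), names(assignment))
  methods::new("MotuPartition", method = method, assignment = a,
               k = length(unique(a)))
}

#' @describeIn motuPartition Named label vector of a partition.
#' @param x A \code{MotuPartition}.
#' @export
motuAssignments <- function(x) x@assignment

#' @describeIn motuPartition Number of MOTUs.
#' @export
motuCount <- function(x) x@k

#' @describeIn motuPartition Producing method label.
#' @export
motuMethod <- function(x) x@method

setMethod("show", "MotuPartition", function(object) {
  cat(sprintf("MotuPartition [%s]: %d sequences in %d MOTUs\n",
              object@method, length(object@assignment), object@k))
})

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult: %d MOTUs from %d schemes (majority > %g)\n",
              object@partition@k, length(object@methods), object@m))
  nIntr <- sum(object@intransitive > 0L)
  if (nIntr) cat(sprintf("  %d MOTU(s) with intransitive votes\n", nIntr))
})

setMethod("show", "PTPModel", function(object) {
  cat(sprintf(
    "PTPModel (%s-rate): k = %d, logL = %.3f (null %.3f), p = %.4g\n",
    object@mode, object@partition@k, object@logL, object@nullLogL,
    object@pValue))
})

setMethod("show", "GMYCModel", function(object) {
  cat(sprintf(
    "GMYCModel (%s): k = %d, logL = %.3f (null %.3f), LR = %.3f, p = %.4g\n",
    object@mode, object@partition@k, object@logL, object@nullLogL,
    object@lrStat, object@pValue))
})

setMethod("show", "ASAPResult", function(object) {
  cat(sprintf("ASAPResult: %d candidate partitions; best k = %d (score %.2f)\n",
              nrow(object@candidates), object@best@k,
              object@candidates$asap_score[1]))
})

setMethod("show", "TruthSet", function(object) {
  cat(sprintf("TruthSet: %d sequences, %d nominal / %d molecular species\n",
              length(object@nominal), length(unique(object@nominal)),
              length(unique(object@molecular))))
})

#' @describeIn motuPartition Truth assignments as MORPHOLOGY-style
#'   partitions: \code{nominal = TRUE} gives the morphology-like labels.
#' @param truth A [TruthSet-class].
#' @param nominal Use nominal (morphology-like) labels rather than the
#'   molecular truth.
#' @export
truthPartition <- function(truth, nominal = TRUE) {
  motuPartition("MORPHOLOGY",
                if (nominal) truth@nominal else truth@molecular)
}
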