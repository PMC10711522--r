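#' Majority-rule consensus over delimitation schemes
#'
#' Two sequences share a consensus MOTU edge when they co-occur in a MOTU
#' in strictly more than \code{m} of the voting schemes; consensus MOTUs
#' are the connected components of that graph. A tie at exactly
#' \code{m} (e.g. 2 of 4) creates no edge, leaning towards splitting -
#' the conservative direction for flagging candidate cryptic lineages.
#' Components may contain pairs that did not themselves reach a majority
#' (intransitivity); these are not re-split, only counted and reported.
#' Morphological species labels can be included as one of the voting
#' schemes by passing them as a \code{MORPHOLOGY} partition.
#'
#' @param partitions List of two or more [MotuPartition-class] objects
#'   over the same sequence id set.
#' @param m Majority fraction (default 0.5).
#' @return A [ConsensusResult-class].
#' @export
consensusPartition <- function(partitions, m = 0.5) {
  if (length(partitions) < 2L) stop("need at least two partitions")
  ids <- names(partitions[[1]]@assignment)
  for (p in partitions[-1])
    if (!setequal(names(p@assignment), ids))
      stop("partitions cover different sequence id sets")
  n <- length(ids)
  votes <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (p in partitions) {
    a <- p@assignment[ids]
    votes <- votes + outer(a, a, `==`)
  }
  diag(votes) <- length(partitions)
  edge <- votes > m * length(partitions)
  idx <- which(edge & upper.tri(edge), arr.ind = TRUE)
  comp <- .components(n, idx)
  part <- motuPartition("CONSENSUS", .labelByFirst(comp, ids, "CON"))
  labels <- part@assignment
  intr <- vapply(split(seq_len(n), comp), function(member) {
    if (length(member) < 2L) return(0L)
    sub <- edge[member, member]
    sum(!sub[upper.tri(sub)])
  }, integer(1))
  names(intr) <- labels[match(as.integer(names(intr)), comp)]
  methods::new("ConsensusResult", partition = part, votes = votes,
               m = m, methods = vapply(partitions, motuMethod,
                                       character(1)),
               intransitive = intr)
}

#' Species-versus-MOTU conflict report
#'
#' Classifies every labelled species against a consensus partition:
#' a \emph{split} species maps to more than one consensus MOTU, a
#' \emph{lump} shares its MOTU with another species, and a \emph{match}
#' corresponds one-to-one. A species that is both split and lumped is
#' counted as a split (and flagged). Barcode-gap distances from
#' [speciesGapTable()] are attached where available.
#'
#' @param consensus A [ConsensusResult-class] (or consensus
#'   [MotuPartition-class]).
#' @param species Named species labels (\code{NA} ignored), as from
#'   [speciesLabels()].
#' @param gapTable Optional output of [speciesGapTable()].
#' @return List with \code{classification} (per-species data.frame:
#'   \code{species, n_seqs, n_motus, category, also_lumped, max_intra,
#'   nn_dist}), \code{splits}, \code{lumps} (per-MOTU data.frame of
#'   lumped species) and \code{summary} (category counts).
#' @export
conflictReport <- function(consensus, species, gapTable = NULL) {
  part <- if (methods::is(consensus, "ConsensusResult"))
    consensus@partition else consensus
  a <- part@assignment
  species <- species[names(a)]
  lab <- !is.na(species)
  spNames <- unique(species[lab])
  motuSpecies <- lapply(split(species[lab], a[lab]),
                        function(v) unique(v))
  rows <- lapply(spNames, function(s) {
    motus <- unique(a[lab & species == s])
    lumped <- any(vapply(motuSpecies[motus], function(v)
      length(v) > 1L, logical(1)))
    category <- if (length(motus) > 1L) "split"
                else if (lumped) "lump" else "match"
    data.frame(species = s, n_seqs = sum(lab & species == s),
               n_motus = length(motus), category = category,
               also_lumped = category == "split" && lumped,
               stringsAsFactors = FALSE)
  })
  cls <- do.call(rbind, rows)
  if (!is.null(gapTable))
    cls <- cbind(cls, gapTable[match(cls$species, gapTable$species),
                               c("max_intra", "nn_dist")])
  lumpMotus <- names(motuSpecies)[vapply(motuSpecies, length,
                                         integer(1)) > 1L]
  lumps <- if (length(lumpMotus))
    data.frame(motu = lumpMotus,
               species = vapply(motuSpecies[lumpMotus], paste,
                                character(1), collapse = "; "),
               n_species = vapply(motuSpecies[lumpMotus], length,
                                  integer(1)),
               stringsAsFactors = FALSE)
  else data.frame(motu = character(0), species = character(0),
                  n_species = integer(0))
  rownames(cls) <- NULL
  list(classification = cls,
       splits = cls[cls$category == "split", , drop = FALSE],
       lumps = lumps,
       summary = c(match = sum(cls$category == "match"),
                   split = sum(cls$category == "split"),
                   lump = sum(cls$category == "lump")))
}
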