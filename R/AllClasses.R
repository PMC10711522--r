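#' ReferenceLibrary: an aligned barcode library with specimen metadata
#'
#' An S4 container coupling an aligned set of DNA barcode sequences
#' (a [Biostrings::DNAStringSet] whose names are the sequence ids) with a
#' specimen metadata table carrying taxonomy and provenance. All sequences
#' share one alignment length; ids are unique; taxonomic ranks are
#' consistent (a species never maps to two genera, a genus never to two
#' families, a family never to two orders).
#'
#' @slot sequences A named \code{DNAStringSet}; equal widths, unique names.
#' @slot metadata A \code{data.frame} with one row per sequence, columns
#'   \code{sequence_id, species, genus, family, order, source, site}.
#'   Unidentified records carry \code{NA} species.
#'
#' @seealso [referenceLibrary()], [readLibrary()]
#' @exportClass ReferenceLibrary
setClass("ReferenceLibrary",
  slots = c(sequences = "DNAStringSet", metadata = "data.frame"))

.metadataCols <- c("sequence_id", "species", "genus", "family", "order",
                   "source", "site")

.checkRankConsistency <- function(md) {
  pairs <- list(c("species", "genus"), c("genus", "family"),
                c("family", "order"))
  for (p in pairs) {
    lo <- md[[p[1]]]; hi <- md[[p[2]]]
    keep <- !is.na(lo)
    if (!any(keep)) next
    tab <- unique(data.frame(lo = lo[keep], hi = hi[keep],
                             stringsAsFactors = FALSE))
    dup <- unique(tab$lo[duplicated(tab$lo)])
    if (length(dup))
      return(sprintf("inconsistent taxonomy: %s '%s' mapped to multiple %s",
                     p[1], paste(dup, collapse = "', '"), p[2]))
  }
  TRUE
}

setValidity("ReferenceLibrary", function(object) {
  seqs <- object@sequences
  md <- object@metadata
  if (length(seqs) < 1L) return("library must contain at least one record")
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    return("all sequences must be named")
  if (anyDuplicated(ids))
    return(sprintf("duplicate sequence ids: %s",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L)
    return(sprintf("alignment error: sequence lengths differ (%s)",
                   paste(range(w), collapse = "-")))
  if (!all(.metadataCols %in% colnames(md)))
    return(sprintf("metadata must contain columns: %s",
                   paste(.metadataCols, collapse = ", ")))
  if (nrow(md) != length(seqs) || !identical(md$sequence_id, ids))
    return("metadata rows must match sequence ids (same order)")
  .checkRankConsistency(md)
})

#' MotuPartition: an assignment of every sequence to a MOTU
#'
#' @slot method Character scalar naming the producing method (one of
#'   \code{"SLC"}, \code{"ASAP"}, \code{"PTP"}, \code{"mPTP"}, \code{"GMYC"},
#'   \code{"mGMYC"}, \code{"MORPHOLOGY"}, \code{"CONSENSUS"}).
#' @slot assignment Named character vector: sequence id -> MOTU label.
#'   Total: every id labelled exactly once.
#' @slot k Integer, number of distinct MOTU labels.
#' @seealso [motuPartition()]
#' @exportClass MotuPartition
setClass("MotuPartition",
  slots = c(method = "character", assignment = "character", k = "integer"))

setValidity("MotuPartition", function(object) {
  a <- object@assignment
  if (length(a) < 1L) return("empty assignment")
  if (is.null(names(a)) || anyDuplicated(names(a)))
    return("assignment must be named with unique sequence ids")
  if (anyNA(a)) return("assignment must be total (no NA labels)")
  if (object@k != length(unique(a)))
    return("k must equal the number of distinct labels")
  if (length(object@method) != 1L) return("method must be a scalar")
  TRUE
})

#' ASAPResult: ranked candidate partitions from hierarchical gap scoring
#'
#' @slot candidates data.frame with one row per candidate threshold:
#'   \code{threshold, k, p_panmixia, W, rank_p, rank_W, asap_score}.
#' @slot partitions List of named label vectors, parallel to
#'   \code{candidates} rows.
#' @slot best The best-scoring [MotuPartition-class].
#' @exportClass ASAPResult
setClass("ASAPResult",
  slots = c(candidates = "data.frame", partitions = "list",
            best = "MotuPartition"))

#' PTPModel: fitted Poisson tree process delimitation
#'
#' @slot partition The delimitation returned (null k = 1 when the one-rate
#'   null is not rejected).
#' @slot lambdaSp Speciation-class exponential rate.
#' @slot lambdaCoal Coalescent-class rate(s): length one in single-rate
#'   mode, one per multi-sequence MOTU in multi-rate mode.
#' @slot logL,nullLogL Log-likelihood of the fitted and one-rate null model.
#' @slot pValue Parametric-bootstrap p-value against the one-rate null.
#' @slot aic AIC of the fitted model (rates + boundary nodes as parameters).
#' @slot mode \code{"single"} or \code{"multi"}.
#' @exportClass PTPModel
setClass("PTPModel",
  slots = c(partition = "MotuPartition", lambdaSp = "numeric",
            lambdaCoal = "numeric", logL = "numeric", nullLogL = "numeric",
            pValue = "numeric", aic = "numeric", mode = "character"))

#' GMYCModel: fitted general mixed Yule-coalescent delimitation
#'
#' @slot partition The delimitation returned (k = 1 when the
#'   single-coalescent null is not rejected).
#' @slot threshold Threshold height(s) separating diversification from
#'   coalescent branching (numeric(0) for the null).
#' @slot lambdaYule,pYule Diversification rate and exponent.
#' @slot lambdaCoal,pCoal Coalescent rate and exponent.
#' @slot logL,nullLogL Maximised and null log-likelihood.
#' @slot lrStat,pValue Likelihood-ratio statistic and its p-value
#'   (chi-square mixture, or parametric bootstrap).
#' @slot mode \code{"single"} or \code{"multiple"}.
#' @slot details List with the per-candidate scan table and fit internals.
#' @exportClass GMYCModel
setClass("GMYCModel",
  slots = c(partition = "MotuPartition", threshold = "numeric",
            lambdaYule = "numeric", pYule = "numeric",
            lambdaCoal = "numeric", pCoal = "numeric",
            logL = "numeric", nullLogL = "numeric",
            lrStat = "numeric", pValue = "numeric",
            mode = "character", details = "list"))

#' ConsensusResult: majority-rule consensus over method partitions
#'
#' @slot partition Consensus [MotuPartition-class] (method "CONSENSUS").
#' @slot votes Symmetric matrix of pairwise co-membership counts.
#' @slot m Majority fraction used.
#' @slot methods Methods that voted.
#' @slot intransitive Named integer: per consensus MOTU, the number of
#'   within-component pairs that did not themselves reach a majority.
#' @exportClass ConsensusResult
setClass("ConsensusResult",
  slots = c(partition = "MotuPartition", votes = "matrix", m = "numeric",
            methods = "character", intransitive = "integer"))

#' TruthSet: ground truth attached to a simulated library
#'
#' @slot nominal Named character: morphology-like species labels (what a
#'   taxonomist would record; cryptic lineages share one nominal label).
#' @slot molecular Named character: the molecular truth (cryptic lineages
#'   distinct).
#' @slot genealogy Ultrametric \code{phylo} over all sequence ids
#'   (heights in substitutions/site).
#' @slot speciesTree Ultrametric \code{phylo} over species.
#' @slot config The [simConfig()] list that generated the library.
#' @exportClass TruthSet
setClass("TruthSet",
  slots = c(nominal = "character", molecular = "character",
            genealogy = "ANY", speciesTree = "ANY", config = "list"))

setValidity("TruthSet", function(object) {
  if (is.null(names(object@nominal)) || anyNA(object@nominal))
    return("nominal assignment must be a complete named vector")
  if (!identical(sort(names(object@nominal)), sort(names(object@molecular))))
    return("nominal and molecular assignments must cover the same ids")
  if (inherits(object@genealogy, "phylo")) {
    if (!setequal(object@genealogy$tip.label, names(object@nominal)))
      return("genealogy leaf set must equal the assigned ids")
  }
  TRUE
})
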