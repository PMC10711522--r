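#' Hierarchical distance partitioning ranked by gap width and panmixia
#'
#' Candidate partitions are the distinct single-linkage merge levels of
#' the pairwise distances (the all-singleton and the single-cluster
#' partitions are always among them). Each candidate is scored twice:
#'
#' * \code{p_panmixia}: a hazard-type panmixia probability for the
#'   first merge the candidate declines. Within panmictic groups,
#'   single-linkage join heights accumulate without large multiplicative
#'   jumps; under a memoryless null whose scale is the deepest join the
#'   candidate accepted (floored at the smallest positive pairwise
#'   distance, the data's resolution), the probability that the groups
#'   would stay separate until the next merge height \code{h_next} is
#'   \code{exp(-(h_next - h_ref)/h_ref)}. A barcode gap makes this jump
#'   ten-fold or more and the probability collapses; within-species and
#'   deep-backbone merges jump by factors of 2-3 and score moderately.
#'   The score depends only on two order statistics, so it is
#'   insensitive to group sizes and to the heavy ties that
#'   haplotype-identical sequences create. Ranked ascending; the
#'   single-cluster candidate (which declines nothing) ranks last.
#' * \code{W}: the gap between the partition's largest intra-group
#'   distance and the next larger pairwise distance, divided by that
#'   largest intra-group distance (floored at the data's resolution) -
#'   the barcode-gap width relative to the divergence scale it sits
#'   above, so a 4% gap over 0.4% intra-group distances outweighs an
#'   equally wide gap between deep backbone clades. Ranked descending.
#'
#' \code{asap_score} is the mean of the two ranks and the candidate list
#' is returned sorted by ascending score (ties broken by larger
#' \code{W}, then smaller \code{k}). The jump statistics (\code{h_ref},
#' \code{h_next}) stay in the candidate table for audit.
#'
#' @param d K2P matrix from [k2pMatrix()] (undefined cells are imputed
#'   with the matrix maximum).
#' @return An [ASAPResult-class]; \code{@best} holds the top-ranked
#'   partition with method \code{"ASAP"}.
#' @export
asapPartitions <- function(d) {
  if (nrow(d) < 2L) stop("at least two sequences are required")
  ids <- rownames(d)
  n <- length(ids)
  dd <- .imputeMatrix(d)
  off <- sort(dd[upper.tri(dd)])
  if (length(unique(off)) == 1L) {
    warning("all pairwise distances are equal; a single merge level exists")
    lab <- stats::setNames(rep(1L, n), ids)
    best <- motuPartition("ASAP", .labelByFirst(lab, ids, "ASAP"))
    return(methods::new(
      "ASAPResult",
      candidates = data.frame(threshold = off[1], k = 1L,
                              p_panmixia = NA_real_, h_ref = NA_real_,
                              h_next = NA_real_, W = NA_real_,
                              rank_p = 1, rank_W = 1, asap_score = 1),
      partitions = list(lab), best = best))
  }
  hc <- stats::hclust(stats::as.dist(dd), method = "single")
  thresholds <- c(-1e-12, sort(unique(hc$height)))
  labs <- lapply(thresholds, function(t) {
    if (t < 0) stats::setNames(seq_len(n), ids)
    else stats::setNames(stats::cutree(hc, h = t), ids)
  })
  nC <- length(thresholds)
  minPos <- min(off[off > 1e-12])
  score <- lapply(seq_len(nC), function(i) {
    t <- thresholds[i]
    lb <- labs[[i]]
    groups <- split(seq_len(n), lb)
    intra <- lapply(groups, function(g)
      if (length(g) >= 2L) dd[g, g][upper.tri(diag(length(g)))]
      else numeric(0))
    pool <- unlist(intra)
    dmax <- if (length(pool)) max(pool) else 0
    acc <- hc$height[hc$height <= t + 1e-12]
    hRef <- max(c(acc, minPos))
    hNext <- if (i < nC) thresholds[i + 1L] else NA_real_
    p <- if (is.na(hNext)) NA_real_
         else min(1, exp(-(hNext - hRef) / hRef))
    above <- off[off > dmax + 1e-12]
    W <- if (!length(above)) NA_real_
         else (above[1] - dmax) / max(dmax, minPos)
    c(k = length(groups), p = p, hRef = hRef, hNext = hNext, W = W)
  })
  sc <- do.call(rbind, score)
  rankNAworst <- function(v, desc = FALSE) {
    r <- rank(if (desc) -v else v, ties.method = "average",
              na.last = "keep")
    r[is.na(r)] <- length(v)
    r
  }
  rankP <- rankNAworst(sc[, "p"])
  rankW <- rankNAworst(sc[, "W"], desc = TRUE)
  asap <- (rankP + rankW) / 2
  cand <- data.frame(threshold = thresholds, k = as.integer(sc[, "k"]),
                     p_panmixia = sc[, "p"], h_ref = sc[, "hRef"],
                     h_next = sc[, "hNext"], W = sc[, "W"],
                     rank_p = rankP, rank_W = rankW, asap_score = asap)
  ord <- order(asap, -ifelse(is.na(cand$W), -Inf, cand$W), cand$k)
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  labs <- labs[ord]
  best <- motuPartition("ASAP", .labelByFirst(unname(labs[[1]]), ids, "ASAP"))
  methods::new("ASAPResult", candidates = cand, partitions = labs,
               best = best)
}
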