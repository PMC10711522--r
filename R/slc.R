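.components <- function(n, edges) {
  # union-find; edges is a 2-column index matrix
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  vapply(seq_len(n), find, integer(1))
}

.labelByFirst <- function(comp, ids, prefix) {
  first <- match(unique(comp), comp)
  lab <- sprintf("%s_%03d", prefix, match(comp, comp[sort(first)]))
  stats::setNames(lab, ids)
}

#' Threshold single-linkage MOTU clustering
#'
#' Connected components of the graph joining sequences at K2P distance
#' \code{<= threshold}. The default 2.2% is the seed threshold used by
#' BIN-style barcode clustering; this function is an explicit
#' single-linkage stand-in for that proprietary algorithm and is labelled
#' \code{SLC}, never BIN. Undefined (saturated) cells never create edges.
#'
#' An optional refinement pass re-examines each component: the component
#' is cut at its widest internal single-linkage merge gap and the split
#' is kept when its mean silhouette width is at least 0.5. Refined
#' components are recorded in the \code{refined} attribute of the
#' returned partition's assignment.
#'
#' @param d K2P matrix from [k2pMatrix()].
#' @param threshold Linkage threshold (substitutions/site).
#' @param refine Apply the silhouette refinement pass (default off).
#' @return A [MotuPartition-class] with method \code{"SLC"}.
#' @export
slcCluster <- function(d, threshold = 0.022, refine = FALSE) {
  ids <- rownames(d)
  n <- length(ids)
  adj <- which(!is.na(d) & d <= threshold & upper.tri(d), arr.ind = TRUE)
  comp <- .components(n, adj)
  refined <- character(0)
  if (refine) {
    for (cc in unique(comp)) {
      idx <- which(comp == cc)
      if (length(idx) < 3L) next
      sub <- d[idx, idx]
      sub[is.na(sub)] <- max(sub, na.rm = TRUE) * 2
      hc <- stats::hclust(stats::as.dist(sub), method = "single")
      hts <- sort(hc$height)
      if (length(hts) < 2L) next
      gaps <- diff(hts)
      g <- which.max(gaps)
      cut <- stats::cutree(hc, h = hts[g] + gaps[g] / 2)
      if (length(unique(cut)) < 2L) next
      sil <- cluster::silhouette(cut, dmatrix = sub)
      if (mean(sil[, "sil_width"]) >= 0.5) {
        comp[idx] <- max(comp) + cut
        refined <- c(refined, ids[idx[1]])
      }
    }
  }
  p <- motuPartition("SLC", .labelByFirst(comp, ids, "SLC"))
  attr(p@assignment, "refined") <- refined
  p
}
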