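.imputeMatrix <- function(d) {
  if (anyNA(d)) {
    mx <- max(d, na.rm = TRUE)
    warning(sum(is.na(d[upper.tri(d)])),
            " undefined (saturated) distance cell(s) imputed with the ",
            "matrix maximum ", signif(mx, 4))
    d[is.na(d)] <- mx
  }
  d
}

#' Neighbour-joining tree from a K2P distance matrix
#'
#' Saitou-Nei neighbour joining (via [ape::nj()]). Undefined cells are
#' imputed with the matrix maximum (with a warning) since NJ needs a
#' complete matrix. Negative branch lengths are clamped to zero and the
#' deficit transferred to the sibling branch so tip-to-tip path lengths
#' through the pair are preserved.
#'
#' @param d Symmetric distance matrix with ids as dimnames (>= 3 ids).
#' @return An unrooted metric \code{phylo}.
#' @export
njTree <- function(d) {
  if (nrow(d) < 3L) stop("neighbour joining needs at least 3 sequences")
  tr <- ape::nj(.imputeMatrix(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    parent <- tr$edge[e, 1]
    sib <- which(tr$edge[, 1] == parent & seq_along(tr$edge.length) != e)
    if (length(sib)) tr$edge.length[sib[1]] <-
        tr$edge.length[sib[1]] + deficit
    tr$edge.length[e] <- 0
  }
  tr
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration; node heights are half the merge
#' distance, so the result is rooted and ultrametric. Stands in for an
#' externally supplied time-calibrated tree wherever one is not given.
#'
#' @inheritParams njTree
#' @return A rooted ultrametric \code{phylo}.
#' @export
upgmaTree <- function(d) {
  if (nrow(d) < 3L) stop("UPGMA needs at least 3 sequences")
  phangorn::upgma(stats::as.dist(.imputeMatrix(d)))
}

#' Node heights of a rooted tree (distance above the tips)
#'
#' @param tree Rooted \code{phylo}.
#' @return Numeric vector over all nodes (tips first, then internal
#'   nodes), giving each node's height above the deepest tip level.
#' @keywords internal
.nodeHeights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Check a tree for ultrametricity
#'
#' @param tree Rooted \code{phylo}.
#' @param tol Absolute tolerance on root-to-tip path spread.
#' @return TRUE, or an attribute-carrying FALSE naming the worst leaf.
#' @export
isUltrametric <- function(tree, tol = 1e-8) {
  h <- .nodeHeights(tree)[seq_along(tree$tip.label)]
  worst <- which.max(abs(h))
  ok <- abs(h[worst]) <= tol
  structure(ok, worst_leaf = tree$tip.label[worst],
            deviation = abs(h[worst]))
}

#' Convert substitution-scale divergence to time at a strict clock
#'
#' At a pairwise clock rate of \code{rate} substitutions/site per million
#' years between two lineages (default 1.2%/Myr, a standard COI
#' calibration), a pairwise divergence \code{d} corresponds to
#' \code{d / rate} million years since the common ancestor. For reporting
#' only; no analysis in the package depends on it.
#'
#' @param d Pairwise divergence(s), substitutions/site.
#' @param rate Pairwise divergence accumulated per million years.
#' @return Ages in million years.
#' @export
divergenceToMyr <- function(d, rate = 0.012) d / rate

#' Collapse identical sequences into haplotypes
#'
#' Sequences identical at all jointly resolved sites (gaps, N and other
#' ambiguity codes are not compared) are merged; the representative is
#' the first member in input order. Compatibility is not transitive in
#' the presence of missing data, so merging is closed transitively
#' (union-find over compatible pairs).
#'
#' @param library A [ReferenceLibrary-class].
#' @return List with \code{library} (the reduced library),
#'   \code{map} (data.frame \code{haplotype, member}) and
#'   \code{multiplicity} (named integer per haplotype representative).
#' @export
collapseHaplotypes <- function(library) {
  codes <- .encodeLibrary(library)
  n <- nrow(codes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      ok <- codes[i, ] > 0L & codes[j, ] > 0L
      if (!any(codes[i, ok] != codes[j, ok])) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  ids <- seqIds(library)
  reps <- ids[sort(unique(root))]
  map <- data.frame(haplotype = ids[root], member = ids,
                    stringsAsFactors = FALSE)
  list(library = subsetLibrary(library, reps), map = map,
       multiplicity = stats::setNames(
         as.integer(table(factor(ids[root], levels = reps))), reps))
}

#' Re-expand a haplotype-level partition to all sequences
#'
#' @param partition A [MotuPartition-class] over haplotype representatives.
#' @param map The \code{map} from [collapseHaplotypes()].
#' @return A \code{MotuPartition} over all member ids.
#' @export
expandPartition <- function(partition, map) {
  a <- motuAssignments(partition)[map$haplotype]
  motuPartition(motuMethod(partition), stats::setNames(a, map$member))
}
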