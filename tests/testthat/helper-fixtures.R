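# Shared fixtures and small independent oracles.

ariOf <- function(partition, truth) {
  a <- motuAssignments(partition)
  mclust::adjustedRandIndex(a[names(truth)], truth)
}

samePartition <- function(partition, truth) {
  isTRUE(all.equal(ariOf(partition, truth), 1))
}

# Hand-built 6-sequence, 3-species toy library (aligned, 60 bp).
toyLibrary <- function() {
  base <- paste(rep("ACGTACGTAC", 6), collapse = "")
  mut <- function(s, pos, to) {
    substr(s, pos, pos) <- to
    s
  }
  seqs <- c(
    a1 = base,
    a2 = mut(base, 1, "G"),                    # one transition from a1
    b1 = mut(mut(base, 10, "A"), 20, "A"),
    b2 = mut(mut(mut(base, 10, "A"), 20, "A"), 30, "T"),
    c1 = mut(mut(mut(mut(base, 5, "T"), 15, "T"), 25, "G"), 35, "G"),
    c2 = mut(mut(mut(mut(mut(base, 5, "T"), 15, "T"), 25, "G"), 35, "G"),
             45, "C"))
  md <- data.frame(
    sequence_id = names(seqs),
    species = c("SpA", "SpA", "SpB", "SpB", "SpC", "SpC"),
    genus = c("G1", "G1", "G1", "G1", "G2", "G2"),
    family = "F1", order = "O1", source = "trawl", site = "s",
    stringsAsFactors = FALSE)
  referenceLibrary(seqs, md)
}

# Independent per-pair K2P oracle: plain character loop, own tables.
bruteK2P <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  pur <- c("A", "G")
  pyr <- c("C", "T")
  ts <- tv <- m <- 0L
  for (i in seq_along(av)) {
    x <- av[i]; y <- bv[i]
    if (!(x %in% c(pur, pyr)) || !(y %in% c(pur, pyr))) next
    m <- m + 1L
    if (x == y) next
    if ((x %in% pur && y %in% pur) || (x %in% pyr && y %in% pyr))
      ts <- ts + 1L
    else tv <- tv + 1L
  }
  if (m == 0L) return(NA_real_)
  P <- ts / m; Q <- tv / m
  if ((1 - 2 * P - Q) <= 0 || (1 - 2 * Q) <= 0) return(NA_real_)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Independent GMYC likelihood: brute-force lineage counting at interval
# midpoints, for continuous (tie-free) ultrametric trees.
naiveGmycLogL <- function(tree, threshold, ly, py, lc, pc) {
  nTip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth) - depth
  h[seq_len(nTip)] <- 0
  parent <- integer(length(h))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  # cluster root of every tip under the threshold
  clusterRoot <- vapply(seq_len(nTip), function(tip) {
    v <- tip
    while (parent[v] != 0L && h[parent[v]] <= threshold) v <- parent[v]
    v
  }, integer(1))
  tipCluster <- clusterRoot
  # each edge belongs to the cluster its parent node sits in, else Yule
  edgeCluster <- vapply(seq_len(nrow(tree$edge)), function(e) {
    p <- tree$edge[e, 1]
    for (cr in unique(tipCluster)) {
      if (cr <= nTip) next
      sub <- ape::extract.clade(tree, cr)
      nodes <- c(ape::getMRCA(tree, sub$tip.label),
                 which(tree$tip.label %in% sub$tip.label))
      # collect all nodes of the clade
      cl <- nodes[1]
      desc <- integer(0)
      stack <- cl
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        desc <- c(desc, v)
        stack <- c(stack, tree$edge[tree$edge[, 1] == v, 2])
      }
      if (p %in% desc) return(cr)
    }
    0L
  }, integer(1))
  events <- sort(h[(nTip + 1L):length(h)], decreasing = TRUE)
  logL <- 0
  for (i in seq_along(events)) {
    top <- events[i]
    bottom <- if (i < length(events)) events[i + 1L] else 0
    mid <- (top + bottom) / 2
    crossing <- which(h[tree$edge[, 2]] <= mid &
                        h[tree$edge[, 1]] > mid)
    nY <- sum(edgeCluster[crossing] == 0L)
    coal <- 0
    for (cr in unique(tipCluster)) {
      nk <- sum(edgeCluster[crossing] == cr)
      if (nk > 1) coal <- coal + nk * (nk - 1)^pc
    }
    b <- ly * (if (nY >= 1) nY^py - 1 else 0) + lc * coal
    logL <- logL + log(b) - b * (top - bottom)
  }
  logL
}
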