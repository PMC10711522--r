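# Coalescent-within-Yule barcode library simulator.
#
# A Yule tree over species is rescaled so that every species split is at
# least `stemScale` above the tips and the crown sits at `crownDepth`
# (heights in substitutions/site; pairwise divergence = 2 x MRCA height).
# Within each species a Kingman coalescent genealogy is grafted whose
# edge scale makes the expected conspecific pairwise divergence equal to
# theta. Sequences evolve along the combined genealogy under a strict
# clock and the K80 model, so the K2P estimator is exactly matched to
# the generative process and divergence targets are analytic.

#' Simulation configuration
#'
#' Defaults emulate the statistical structure of a regional fish COI
#' reference library: mean conspecific divergence theta = 0.0036, a
#' minimum between-species divergence of 5% with congeneric divergences
#' around 7% and family-level divergences extending to ~30% (crown
#' height 0.15), 652 bp alignments, and 1-23 sequences per species with
#' mean 4 (truncated-geometric sampling).
#'
#' @param nSpecies Number of species.
#' @param seqsMin,seqsMax,seqsMean Truncated-geometric sampling
#'   distribution of sequences per species.
#' @param birthRate Yule birth rate (shapes the species tree before
#'   rescaling).
#' @param theta Expected conspecific pairwise divergence
#'   (substitutions/site).
#' @param stemScale Minimum species-split height; the minimum
#'   between-species divergence is \code{2 * stemScale}.
#' @param crownDepth Root height of the species tree; maximum
#'   between-species divergence is \code{2 * crownDepth}.
#' @param kappa K80 transition/transversion rate ratio.
#' @param seqLength Alignment length in bp (>= 100).
#' @param clockRate Pairwise divergence per million years (reporting
#'   only; see [divergenceToMyr()]).
#' @param seed Integer seed; the same seed reproduces the library
#'   byte-for-byte.
#' @return A list of class \code{simConfig}.
#' @export
simConfig <- function(nSpecies = 20, seqsMin = 1, seqsMax = 23,
                      seqsMean = 4, birthRate = 1, theta = 0.0036,
                      stemScale = 0.025, crownDepth = 0.15, kappa = 4,
                      seqLength = 652, clockRate = 0.012, seed = 1) {
  cfg <- list(nSpecies = as.integer(nSpecies), seqsMin = as.integer(seqsMin),
              seqsMax = as.integer(seqsMax), seqsMean = seqsMean,
              birthRate = birthRate, theta = theta, stemScale = stemScale,
              crownDepth = crownDepth, kappa = kappa,
              seqLength = as.integer(seqLength), clockRate = clockRate,
              seed = as.integer(seed))
  if (cfg$nSpecies < 1L) stop("nSpecies must be >= 1")
  if (cfg$seqLength < 100L) stop("seqLength must be >= 100")
  if (any(c(cfg$birthRate, cfg$theta, cfg$kappa, cfg$clockRate) <= 0))
    stop("all rates must be > 0")
  if (cfg$stemScale >= cfg$crownDepth)
    stop("stemScale must be smaller than crownDepth")
  if (cfg$seqsMean < cfg$seqsMin || cfg$seqsMean > cfg$seqsMax)
    stop("seqsMean must lie within [seqsMin, seqsMax]")
  class(cfg) <- "simConfig"
  cfg
}

# weight ratio of a (possibly increasing) geometric on {min..max} with
# the given mean; q = 1 is the uniform (mean at the midpoint)
.truncGeomQ <- function(minK, maxK, meanK) {
  ks <- minK:maxK
  if (minK == maxK) return(1)
  mid <- (minK + maxK) / 2
  if (abs(meanK - mid) < 1e-9) return(1)
  f <- function(q) sum(ks * q^(ks - minK)) / sum(q^(ks - minK)) - meanK
  if (meanK < mid) stats::uniroot(f, c(1e-9, 1 - 1e-9))$root
  else stats::uniroot(f, c(1 + 1e-9, 100))$root
}

.sampleSeqsPerSpecies <- function(cfg) {
  ks <- cfg$seqsMin:cfg$seqsMax
  if (length(ks) == 1L) return(rep(ks, cfg$nSpecies))
  q <- .truncGeomQ(cfg$seqsMin, cfg$seqsMax, cfg$seqsMean)
  w <- q^(ks - cfg$seqsMin)
  sample(ks, cfg$nSpecies, replace = TRUE, prob = w / sum(w))
}

.rebuildEdgeLengths <- function(tree, heights) {
  tree$edge.length <- heights[tree$edge[, 1]] - heights[tree$edge[, 2]]
  tree
}

# group tips by the topmost ancestor at or below height h
.cladeGroups <- function(tree, h) {
  hts <- .nodeHeights(tree)
  parent <- integer(length(hts))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  vapply(seq_along(tree$tip.label), function(tip) {
    v <- tip
    while (parent[v] != 0L && hts[parent[v]] <= h) v <- parent[v]
    v
  }, integer(1))
}

.simSequences <- function(genealogy, cfg) {
  k <- cfg$kappa
  dat <- phangorn::simSeq(genealogy, l = cfg$seqLength,
                          Q = c(1, k, 1, 1, k, 1), bf = rep(0.25, 4),
                          type = "DNA")
  m <- toupper(as.character(dat))
  seqs <- apply(m, 1, paste, collapse = "")
  Biostrings::DNAStringSet(seqs[genealogy$tip.label])
}

#' Simulate a barcode reference library with known truth
#'
#' Draws a Yule species tree, grafts within-species Kingman coalescent
#' genealogies (expected conspecific divergence = \code{theta}), and
#' evolves a strict-clock K80 alignment along the combined genealogy.
#' Genera and families are defined by cutting the species tree at fixed
#' heights, giving a consistent taxonomy for rank-level summaries.
#' Deterministic under a fixed \code{config$seed}.
#'
#' @param config A [simConfig()].
#' @return List with \code{library} (a [ReferenceLibrary-class]) and
#'   \code{truth} (a [TruthSet-class]).
#' @export
simulateReferenceLibrary <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  cfg <- config
  set.seed(cfg$seed)
  spNames <- sprintf("Species%02d", seq_len(cfg$nSpecies))
  counts <- .sampleSeqsPerSpecies(cfg)
  names(counts) <- spNames

  if (cfg$nSpecies >= 2L) {
    spTree <- ape::rphylo(cfg$nSpecies, birth = cfg$birthRate, death = 0)
    spTree$tip.label <- spNames
    hts <- .nodeHeights(spTree)
    H <- max(hts)
    internal <- (cfg$nSpecies + 1L):(cfg$nSpecies + spTree$Nnode)
    hts[internal] <- cfg$stemScale +
      hts[internal] * (cfg$crownDepth - cfg$stemScale) / H
    spTree <- .rebuildEdgeLengths(spTree, hts)
    genusIdx <- .cladeGroups(spTree, cfg$stemScale +
                               0.2 * (cfg$crownDepth - cfg$stemScale))
    familyIdx <- .cladeGroups(spTree, cfg$stemScale +
                                0.6 * (cfg$crownDepth - cfg$stemScale))
    genus <- sprintf("Genus%02d", match(genusIdx, unique(genusIdx)))
    family <- sprintf("Family%02d", match(familyIdx, unique(familyIdx)))
  } else {
    spTree <- NULL
    genus <- "Genus01"; family <- "Family01"
  }

  # graft within-species coalescent genealogies
  geneTree <- spTree
  for (i in seq_len(cfg$nSpecies)) {
    ids <- sprintf("%s_%02d", spNames[i], seq_len(counts[i]))
    if (counts[i] == 1L) {
      if (is.null(geneTree)) stop("a single species needs >= 2 sequences")
      geneTree$tip.label[geneTree$tip.label == spNames[i]] <- ids
      next
    }
    sub <- ape::rcoal(counts[i], tip.label = ids)
    sub$edge.length <- sub$edge.length * cfg$theta / 2
    maxH <- 0.9 * cfg$stemScale
    hSub <- max(.nodeHeights(sub))
    if (hSub > maxH) sub$edge.length <- sub$edge.length * maxH / hSub
    if (is.null(geneTree)) { geneTree <- sub; next }
    tip <- match(spNames[i], geneTree$tip.label)
    stem <- which(geneTree$edge[, 2] == tip)
    geneTree$edge.length[stem] <-
      geneTree$edge.length[stem] - min(hSub, maxH)
    geneTree <- ape::bind.tree(geneTree, sub, where = tip)
  }

  seqs <- .simSequences(geneTree, cfg)
  ids <- names(seqs)
  spOfId <- sub("_[0-9]+$", "", ids)
  idx <- match(spOfId, spNames)
  metadata <- data.frame(
    sequence_id = ids, species = spOfId,
    genus = if (length(genus) > 1) genus[idx] else genus,
    family = if (length(family) > 1) family[idx] else family,
    order = "SimOrder",
    source = sample(c("trawl", "market", "mined"), length(ids),
                    replace = TRUE, prob = c(0.5, 0.3, 0.2)),
    site = sprintf("site%d", sample.int(5, length(ids), replace = TRUE)),
    stringsAsFactors = FALSE)
  library <- referenceLibrary(seqs, metadata)
  truth <- methods::new("TruthSet",
                        nominal = stats::setNames(spOfId, ids),
                        molecular = stats::setNames(spOfId, ids),
                        genealogy = geneTree, speciesTree = spTree,
                        config = unclass(cfg))
  list(library = library, truth = truth)
}

#' Inject a diagnostic feature into a simulated library
#'
#' Emulates the delimitation edge cases seen in real reference
#' libraries:
#' \describe{
#'   \item{cryptic_split}{One nominal species is given two deep clades
#'     at pairwise divergence ~ \code{depth} (the nominal label stays
#'     single, the molecular truth records two lineages).}
#'   \item{shallow_pair}{A sister species is grafted at divergence
#'     ~ \code{divergence} (distinct in both nominal and molecular
#'     truth - a morphologically diagnosable but barely diverged pair).}
#'   \item{singleton}{One species is pruned to a single sequence, making
#'     its maximum intraspecific distance undefined.}
#' }
#' For the first two features the true genealogy's node heights are
#' edited (ancestor heights raised where needed to stay ultrametric) and
#' the whole alignment is re-simulated from the modified genealogy under
#' the original K80 parameters, so sequences and recorded truth stay
#' exactly consistent.
#'
#' @param sim Output of [simulateReferenceLibrary()].
#' @param feature One of \code{"cryptic_split"}, \code{"shallow_pair"},
#'   \code{"singleton"}.
#' @param species Target species (default: the best-sampled one).
#' @param depth Target intra-"species" divergence of the cryptic split.
#' @param divergence Target divergence of the shallow pair.
#' @param seed Seed for the re-simulation.
#' @return A list like \code{sim}, with modified \code{library} and
#'   \code{truth}.
#' @export
injectFeature <- function(sim, feature = c("cryptic_split", "shallow_pair",
                                           "singleton"),
                          species = NULL, depth = 0.086,
                          divergence = 0.008, seed = 1) {
  feature <- match.arg(feature)
  truth <- sim$truth
  cfg <- do.call(simConfig, truth@config[setdiff(names(truth@config), NULL)])
  tree <- truth@genealogy
  nominal <- truth@nominal
  molecular <- truth@molecular
  counts <- table(nominal)
  if (is.null(species))
    species <- names(counts)[which.max(counts)]
  tips <- names(nominal)[nominal == species]
  set.seed(seed)

  if (feature == "singleton") {
    if (length(tips) < 2L)
      stop(sprintf("species '%s' is too small for feature '%s'",
                   species, feature))
    drop <- tips[-1]
    tree <- ape::drop.tip(tree, drop)
    keep <- setdiff(names(nominal), drop)
    truth2 <- methods::new("TruthSet", nominal = nominal[keep],
                           molecular = molecular[keep], genealogy = tree,
                           speciesTree = truth@speciesTree,
                           config = truth@config)
    return(list(library = subsetLibrary(sim$library, keep), truth = truth2))
  }

  hts <- .nodeHeights(tree)
  parent <- integer(length(hts))
  parent[tree$edge[, 2]] <- tree$edge[, 1]

  if (feature == "cryptic_split") {
    if (length(tips) < 2L)
      stop(sprintf("species '%s' is too small for feature '%s'",
                   species, feature))
    mrca <- ape::getMRCA(tree, tips)
    # the feature targets the observable - the species' realized maximum
    # intraspecific K2P estimate; the maximum over the (correlated,
    # noisy) cross-clade estimates sits ~8-10% above the underlying path
    # length at COI scale, so the injected height is shrunk accordingly
    hts[mrca] <- 0.92 * depth / 2
    v <- mrca
    while (parent[v] != 0L) {            # keep ancestors above the clade
      p <- parent[v]
      hts[p] <- max(hts[p], hts[v] + 1e-6)
      v <- p
    }
    tree <- .rebuildEdgeLengths(tree, hts)
    children <- tree$edge[tree$edge[, 1] == mrca, 2]
    cladeTips <- function(v) {
      if (v <= length(tree$tip.label)) return(tree$tip.label[v])
      ape::extract.clade(tree, v)$tip.label
    }
    clade2 <- cladeTips(children[2])
    molecular[intersect(clade2, tips)] <- paste0(species, "_cryptic")
  } else {                               # shallow_pair
    a <- divergence / 2
    if (length(tips) >= 2L) {
      mrca <- ape::getMRCA(tree, tips)
      if (hts[mrca] >= 0.8 * a) {        # shrink the clade below the graft
        sub <- .preorder(.listChildren(tree), mrca)
        scale <- 0.6 * a / hts[mrca]
        hts[sub] <- hts[sub] * scale
        tree <- .rebuildEdgeLengths(tree, hts)
        hts <- .nodeHeights(tree)
      }
      where <- mrca
    } else {
      where <- match(tips, tree$tip.label)
    }
    newSpecies <- paste0(species, "sister")
    newIds <- sprintf("%s_%02d", newSpecies, 1:2)
    tc <- min(stats::rexp(1) * cfg$theta / 2, 0.6 * a)
    y <- ape::read.tree(text = sprintf("(%s:%.10f,%s:%.10f):%.10f;",
                                       newIds[1], tc, newIds[2], tc,
                                       a - tc))
    tree <- ape::bind.tree(tree, y, where = where,
                           position = a - hts[where])
    nominal <- c(nominal, stats::setNames(rep(newSpecies, 2), newIds))
    molecular <- c(molecular, stats::setNames(rep(newSpecies, 2), newIds))
  }

  seqs <- .simSequences(tree, cfg)
  md <- libraryMetadata(sim$library)
  if (feature == "shallow_pair") {
    tmpl <- md[match(tips[1], md$sequence_id), ]
    extra <- tmpl[rep(1, 2), ]
    extra$sequence_id <- names(nominal)[(length(nominal) - 1):
                                          length(nominal)]
    extra$species <- nominal[extra$sequence_id]
    md <- rbind(md, extra)
  }
  md <- md[match(names(seqs), md$sequence_id), ]
  library <- referenceLibrary(seqs, md)
  truth2 <- methods::new("TruthSet", nominal = nominal[names(seqs)],
                         molecular = molecular[names(seqs)],
                         genealogy = tree,
                         speciesTree = truth@speciesTree,
                         config = truth@config)
  list(library = library, truth = truth2)
}

.listChildren <- function(tree) {
  children <- vector("list", length(tree$tip.label) + tree$Nnode)
  for (e in seq_len(nrow(tree$edge)))
    children[[tree$edge[e, 1]]] <-
      c(children[[tree$edge[e, 1]]], tree$edge[e, 2])
  children
}
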