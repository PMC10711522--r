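test_that("NJ recovers a 4-taxon additive matrix exactly", {
  # edges: A-u 1, B-u 2, u-v 1, C-v 3, D-v 4
  ids <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(ids, ids))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d <- d + t(d)
  tr <- njTree(d)
  path <- ape::cophenetic.phylo(tr)[ids, ids]
  expect_equal(path, d, tolerance = 1e-9)
  # generating topology AB|CD
  expect_true(ape::is.monophyletic(ape::root(tr, "D"), c("A", "B")))
})

test_that("NJ path lengths reproduce random additive matrices", {
  set.seed(11)
  for (i in 1:10) {
    tr0 <- ape::rtree(8)
    tr0$edge.length <- runif(nrow(tr0$edge), 0.05, 1)
    d <- ape::cophenetic.phylo(tr0)
    tr <- njTree(d)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
  }
})

test_that("NJ needs three taxa and imputes undefined cells with a warning", {
  d <- matrix(c(0, .1, .1, 0), 2, dimnames = rep(list(c("a", "b")), 2))
  expect_error(njTree(d), "at least 3")
  d3 <- matrix(0.2, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  diag(d3) <- 0
  d3["a", "b"] <- d3["b", "a"] <- NA
  expect_warning(tr <- njTree(d3), "imputed")
  expect_s3_class(tr, "phylo")
  expect_true(all(tr$edge.length >= 0))
})

test_that("NJ topology recovery holds on simulated one-per-species libraries", {
  # low-divergence quartets with one sequence per species: long
  # alignments keep the K2P noise below the internal-branch scale
  # (random Yule shapes put some branches near zero, so deeper or
  # larger trees cannot support an exact-topology claim at this rate)
  hit <- 0L
  for (s in 1:100) {
    cfg <- simConfig(nSpecies = 4, seqsMin = 1, seqsMax = 1, seqsMean = 1,
                     stemScale = 0.04, crownDepth = 0.12, seqLength = 5000,
                     seed = s)
    sim <- simulateReferenceLibrary(cfg)
    d <- k2pMatrix(sim$library)
    tr <- njTree(d)
    sp <- sim$truth@speciesTree
    tr$tip.label <- sub("_[0-9]+$", "", tr$tip.label)
    if (phangorn::RF.dist(ape::unroot(tr), ape::unroot(sp)) == 0)
      hit <- hit + 1L
  }
  expect_gte(hit, 95L)
})

test_that("UPGMA matches hand agglomeration and is ultrametric", {
  ids <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(ids, ids))
  d["A", "B"] <- 2
  d["A", "C"] <- d["B", "C"] <- 4
  d["A", "D"] <- d["B", "D"] <- d["C", "D"] <- 6
  d <- d + t(d)
  tr <- upgmaTree(d)
  expect_true(isUltrametric(tr, tol = 1e-9))
  # hand steps: AB at height 1, +C at 2, +D at 3
  expect_equal(ape::cophenetic.phylo(tr)[ids, ids], d, tolerance = 1e-9)
  h <- sort(ape::branching.times(tr))
  expect_equal(unname(h), c(1, 2, 3), tolerance = 1e-9)
})

test_that("UPGMA heights are monotone on arbitrary input", {
  set.seed(2)
  n <- 12
  d <- matrix(0, n, n, dimnames = rep(list(paste0("t", 1:n)), 2))
  d[upper.tri(d)] <- runif(choose(n, 2), 0.01, 0.4)
  d <- d + t(d)
  tr <- upgmaTree(d)
  expect_true(isUltrametric(tr, tol = 1e-9))
  depth <- ape::node.depth.edgelength(tr)
  h <- max(depth) - depth
  for (e in seq_len(nrow(tr$edge)))
    expect_gte(h[tr$edge[e, 1]], h[tr$edge[e, 2]] - 1e-12)
})

test_that("haplotype collapsing merges by jointly resolved sites", {
  seqs <- c(h1 = "ACGTACGTAC", h2 = "ACGTACGTAC",  # identical
            h3 = "ACNTACGTAC",                      # N-compatible with h1
            h4 = "TCGTACGTAC")                      # distinct
  md <- data.frame(sequence_id = names(seqs), species = "S", genus = "G",
                   family = "F", order = "O", source = "trawl", site = "s")
  lib <- referenceLibrary(seqs, md)
  col <- collapseHaplotypes(lib)
  expect_equal(seqIds(col$library), c("h1", "h4"))
  expect_equal(col$multiplicity, c(h1 = 3L, h4 = 1L))
  expect_equal(col$map$haplotype[col$map$member == "h3"], "h1")
  # all-distinct input is an identity
  lib2 <- subsetLibrary(lib, c("h1", "h4"))
  col2 <- collapseHaplotypes(lib2)
  expect_equal(seqIds(col2$library), c("h1", "h4"))
  # expansion restores total coverage
  part <- motuPartition("SLC", setNames(c("m1", "m2"), c("h1", "h4")))
  full <- expandPartition(part, col$map)
  expect_setequal(names(motuAssignments(full)), names(seqs))
  expect_equal(unname(motuAssignments(full)[c("h2", "h3")]), c("m1", "m1"))
})

test_that("divergence-to-age conversion applies the strict clock", {
  expect_equal(divergenceToMyr(0.012), 1)
  expect_equal(divergenceToMyr(0.06, rate = 0.012), 5)
})
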