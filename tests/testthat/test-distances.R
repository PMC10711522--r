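test_that("site-pattern counting handles matches, transitions and gaps", {
  expect_equal(countSitePatterns("ACGT", "ACGT"), list(ts = 0, tv = 0, m = 4))
  expect_equal(countSitePatterns("ACGT", "GCGT"), list(ts = 1, tv = 0, m = 4))
  expect_equal(countSitePatterns("ACG-", "ACGT"), list(ts = 0, tv = 0, m = 3))
  # N and ambiguity codes are missing, not mismatches
  expect_equal(countSitePatterns("ANGT", "ARGT"), list(ts = 0, tv = 0, m = 3))
  expect_error(countSitePatterns("ACG", "ACGT"), "equal")
})

test_that("K2P closed form matches hand evaluation and flags saturation", {
  expect_equal(k2pFromCounts(0, 0, 600), 0)
  expect_equal(k2pFromCounts(1, 1, 10), 0.23412335979792, tolerance = 1e-9)
  expect_equal(k2pFromCounts(1, 0, 100), 0.01010135365876, tolerance = 1e-9)
  expect_true(is.na(k2pFromCounts(5, 0, 10)))   # 1 - 2P - Q = 0
  expect_true(is.na(k2pFromCounts(0, 5, 10)))   # 1 - 2Q = 0
  expect_true(is.na(k2pFromCounts(0, 0, 0)))    # no overlap
})

test_that("the distance matrix agrees with the established reference and is symmetric", {
  sim <- simulateReferenceLibrary(simConfig(nSpecies = 5, seed = 21))
  d <- k2pMatrix(sim$library)
  expect_true(isSymmetric(unclass(d)))
  expect_equal(unname(diag(d)), rep(0, nrow(d)))
  bin <- ape::as.DNAbin(Biostrings::DNAMultipleAlignment(
    librarySequences(sim$library)))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(unclass(d)[rownames(ref), colnames(ref)], ref,
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("the K2P estimator is consistent for simulated K80 pairs", {
  # two-lineage divergence delta; mean over replicates within 3 MC se
  delta <- 0.1
  tree <- ape::read.tree(text = sprintf("(a:%f,b:%f);", delta / 2, delta / 2))
  set.seed(7)
  est <- replicate(500, {
    dat <- phangorn::simSeq(tree, l = 652, Q = c(1, 4, 1, 1, 4, 1),
                            bf = rep(0.25, 4), type = "DNA")
    m <- toupper(as.character(dat))
    cnt <- countSitePatterns(paste(m["a", ], collapse = ""),
                             paste(m["b", ], collapse = ""))
    k2pFromCounts(cnt$ts, cnt$tv, cnt$m)
  })
  expect_lt(abs(mean(est) - delta), 3 * sd(est) / sqrt(length(est)))
})

test_that("species gap records match an exhaustive scan on a toy matrix", {
  ids <- c("a1", "a2", "b1", "b2", "c1", "c2")
  sp <- setNames(c("A", "A", "B", "B", "C", "C"), ids)
  # block structure: small within species, distinct levels between
  set.seed(5)
  d <- matrix(0, 6, 6, dimnames = list(ids, ids))
  for (i in 1:5) for (j in (i + 1):6) {
    d[i, j] <- if (sp[i] == sp[j]) runif(1, 0.001, 0.004)
               else if (sp[i] == "A" || sp[j] == "A") runif(1, 0.05, 0.06)
               else runif(1, 0.07, 0.09)
    d[j, i] <- d[i, j]
  }
  gt <- speciesGapTable(d, sp)
  for (s in c("A", "B", "C")) {
    own <- ids[sp == s]; oth <- ids[sp != s]
    expect_equal(gt$max_intra[gt$species == s], max(d[own, own]), info = s)
    expect_equal(gt$nn_dist[gt$species == s], min(d[own, oth]), info = s)
  }
  expect_true(all(gt$gap_present))
  expect_equal(gt$fold, gt$nn_dist / gt$max_intra)
})

test_that("nearest-neighbour distances are reciprocal pool members", {
  sim <- simulateReferenceLibrary(simConfig(nSpecies = 8, seed = 3))
  d <- k2pMatrix(sim$library)
  sp <- speciesLabels(sim$library)
  gt <- speciesGapTable(d, sp)
  for (i in seq_len(nrow(gt))) {
    x <- gt$species[i]; y <- gt$nn_taxon[i]
    het <- d[names(sp)[sp == y], names(sp)[sp == x], drop = FALSE]
    expect_true(any(abs(het - gt$nn_dist[i]) < 1e-12), info = x)
  }
})

test_that("gap records require two labelled species and handle singletons", {
  d <- matrix(c(0, .1, .1, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_error(speciesGapTable(d, setNames(c("A", "A"), c("x", "y"))),
               "two labelled species")
  d3 <- matrix(0.05, 3, 3, dimnames = rep(list(c("x", "y", "z")), 2))
  diag(d3) <- 0
  gt <- speciesGapTable(d3, setNames(c("A", "B", "B"), c("x", "y", "z")))
  expect_true(is.na(gt$max_intra[gt$species == "A"]))  # singleton
  expect_true(is.na(gt$gap_present[gt$species == "A"]))
  expect_true(is.na(gt$fold[gt$species == "A"]))
})

test_that("rank summaries pool exclusively, match a hand tally, and stay disjoint", {
  lib <- toyLibrary()
  d <- k2pMatrix(lib)
  rs <- rankSummaries(d, libraryMetadata(lib))
  ex <- rs[rs$pooling == "exclusive", ]
  # hand tally: conspecific pairs a1a2, b1b2, c1c2
  sp <- mean(c(d["a1", "a2"], d["b1", "b2"], d["c1", "c2"]))
  expect_equal(ex$mean[ex$level == "within_species"], sp)
  expect_equal(ex$n_pairs[ex$level == "within_species"], 3L)
  # genus G1 holds SpA+SpB: 4 heterospecific congeneric pairs
  ge <- mean(c(d["a1", "b1"], d["a1", "b2"], d["a2", "b1"], d["a2", "b2"]))
  expect_equal(ex$mean[ex$level == "within_genus"], ge)
  expect_equal(ex$n_groups[ex$level == "within_genus"], 2L)
  # family pool: G1 x G2 pairs only
  expect_equal(ex$n_pairs[ex$level == "within_family"], 8L)
  # the three exclusive pools partition the classified pairs
  expect_equal(sum(ex$n_pairs), choose(6, 2))
  # inclusive pooling nests the exclusive pools
  inc <- rs[rs$pooling == "inclusive", ]
  # G1 = {a1,a2,b1,b2}: 6 pairs; G2 = {c1,c2}: 1 pair
  expect_equal(inc$n_pairs[inc$level == "within_genus"], 7L)
  expect_equal(inc$n_pairs[inc$level == "within_family"], choose(6, 2))
})

test_that("single-genus libraries yield absent higher-rank summaries", {
  lib <- toyLibrary()
  keep <- c("a1", "a2", "b1", "b2")  # one genus, one family
  sub <- subsetLibrary(lib, keep)
  rs <- rankSummaries(k2pMatrix(sub), libraryMetadata(sub))
  ex <- rs[rs$pooling == "exclusive", ]
  expect_true(is.na(ex$mean[ex$level == "within_family"]))
  expect_equal(ex$n_pairs[ex$level == "within_family"], 0L)
  expect_false(is.na(ex$mean[ex$level == "within_genus"]))
})
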