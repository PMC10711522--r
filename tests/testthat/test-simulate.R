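test_that("simulated libraries satisfy their structural contracts", {
  cfg <- simConfig(nSpecies = 7, seed = 11)
  sim <- simulateReferenceLibrary(cfg)
  lib <- sim$library
  truth <- sim$truth
  expect_s4_class(lib, "ReferenceLibrary")
  expect_s4_class(truth, "TruthSet")
  expect_equal(alignmentLength(lib), 652L)
  counts <- table(truth@nominal)
  expect_equal(length(counts), 7L)
  expect_true(all(counts >= 1 & counts <= 23))
  expect_setequal(names(truth@nominal), seqIds(lib))
  expect_setequal(truth@genealogy$tip.label, seqIds(lib))
  expect_true(isUltrametric(truth@genealogy, tol = 1e-6))
  expect_identical(truth@nominal, truth@molecular)
})

test_that("sequences-per-species sampling hits its moments and bounds", {
  cfg <- simConfig(nSpecies = 2000, seed = 5)
  set.seed(5)
  counts <- motuforge:::.sampleSeqsPerSpecies(cfg)
  expect_true(all(counts >= 1 & counts <= 23))
  expect_equal(mean(counts), 4, tolerance = 0.15)
})

test_that("the same seed reproduces the library byte for byte", {
  cfg <- simConfig(nSpecies = 5, seed = 77)
  f1 <- withr::local_tempfile(); m1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile(); m2 <- withr::local_tempfile()
  writeLibrary(simulateReferenceLibrary(cfg)$library, f1, m1)
  writeLibrary(simulateReferenceLibrary(cfg)$library, f2, m2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(readBin(m1, "raw", file.size(m1)),
                   readBin(m2, "raw", file.size(m2)))
})

test_that("realized conspecific divergence is centred on theta", {
  # fixed 3 sequences per species keeps the estimate comparable across
  # replicates; the replicate mean must sit within 3 MC standard errors
  means <- vapply(1:200, function(s) {
    cfg <- simConfig(nSpecies = 4, seqsMin = 3, seqsMax = 3, seqsMean = 3,
                     seed = 1000 + s)
    sim <- simulateReferenceLibrary(cfg)
    d <- k2pMatrix(sim$library)
    sp <- speciesLabels(sim$library)
    same <- outer(sp, sp, `==`) & upper.tri(d)
    mean(d[same], na.rm = TRUE)
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.0036), 3 * se)
})

test_that("between-species divergence respects the stem floor", {
  sim <- simulateReferenceLibrary(simConfig(nSpecies = 10, seed = 8))
  d <- k2pMatrix(sim$library)
  sp <- speciesLabels(sim$library)
  het <- d[outer(sp, sp, `!=`) & upper.tri(d)]
  # true paths are >= 2 * stemScale = 5%; allow estimator noise
  expect_gt(min(het, na.rm = TRUE), 0.04)
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(nSpecies = 0), "nSpecies")
  expect_error(simConfig(seqLength = 50), "seqLength")
  expect_error(simConfig(theta = -1), "rates")
  expect_error(simConfig(stemScale = 0.2, crownDepth = 0.1), "stemScale")
  expect_error(simConfig(seqsMean = 30), "seqsMean")
})

test_that("cryptic splits create one deep nominal species", {
  sim <- simulateReferenceLibrary(simConfig(nSpecies = 8, seed = 31))
  inj <- injectFeature(sim, "cryptic_split", seed = 99)
  target <- names(which.max(table(sim$truth@nominal)))
  expect_identical(inj$truth@nominal[names(sim$truth@nominal)],
                   sim$truth@nominal)
  expect_equal(length(unique(inj$truth@molecular)),
               length(unique(sim$truth@molecular)) + 1L)
  d <- k2pMatrix(inj$library)
  gt <- speciesGapTable(d, speciesLabels(inj$library))
  expect_gt(gt$max_intra[gt$species == target], 0.05)
  expect_true(isUltrametric(inj$truth@genealogy, tol = 1e-6))
})

test_that("shallow pairs sit below the 1% nearest-neighbour mark", {
  sim <- simulateReferenceLibrary(simConfig(nSpecies = 8, seed = 32))
  inj <- injectFeature(sim, "shallow_pair", divergence = 0.008, seed = 7)
  expect_equal(length(seqIds(inj$library)), length(seqIds(sim$library)) + 2L)
  d <- k2pMatrix(inj$library)
  gt <- speciesGapTable(d, speciesLabels(inj$library))
  expect_lt(min(gt$nn_dist), 0.01)
  expect_true(isUltrametric(inj$truth@genealogy, tol = 1e-6))
  # nominal and molecular truth both carry the new species
  expect_equal(length(unique(inj$truth@nominal)),
               length(unique(sim$truth@nominal)) + 1L)
})

test_that("singleton pruning leaves max-intra undefined", {
  sim <- simulateReferenceLibrary(simConfig(nSpecies = 8, seed = 33))
  target <- names(which.max(table(sim$truth@nominal)))
  inj <- injectFeature(sim, "singleton", species = target)
  expect_equal(sum(inj$truth@nominal == target), 1L)
  d <- k2pMatrix(inj$library)
  gt <- speciesGapTable(d, speciesLabels(inj$library))
  expect_true(is.na(gt$max_intra[gt$species == target]))
  # untouched species keep their original sequences
  keep <- names(sim$truth@nominal)[sim$truth@nominal != target]
  expect_identical(
    as.character(librarySequences(inj$library)[keep]),
    as.character(librarySequences(sim$library)[keep]))
})

test_that("features refuse species that are too small", {
  sim <- simulateReferenceLibrary(
    simConfig(nSpecies = 4, seqsMin = 1, seqsMax = 1, seqsMean = 1,
              seed = 3))
  expect_error(injectFeature(sim, "cryptic_split", seed = 1), "too small")
  expect_error(injectFeature(sim, "singleton"), "too small")
})
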