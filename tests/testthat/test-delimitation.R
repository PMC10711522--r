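# Threshold single-linkage clustering -----------------------------------

test_that("single-linkage clustering honours degenerate thresholds", {
  sim <- simulateReferenceLibrary(simConfig(nSpecies = 6, seed = 2))
  d <- k2pMatrix(sim$library)
  all1 <- slcCluster(d, threshold = max(d, na.rm = TRUE) + 1)
  expect_equal(motuCount(all1), 1L)
  mn <- min(d[upper.tri(d)][d[upper.tri(d)] > 0])
  singletons <- slcCluster(d, threshold = mn / 2)
  # only identical haplotypes may share a cluster below the min distance
  zeroPairs <- d <= 1e-12
  diag(zeroPairs) <- FALSE
  if (!any(zeroPairs)) expect_equal(motuCount(singletons), nrow(d))
})

test_that("single-linkage partitions are monotone in the threshold", {
  sim <- simulateReferenceLibrary(simConfig(nSpecies = 8, seed = 13))
  d <- k2pMatrix(sim$library)
  ths <- c(0.001, 0.005, 0.022, 0.05, 0.1, 0.2)
  parts <- lapply(ths, function(t) motuAssignments(slcCluster(d, t)))
  for (i in seq_len(length(ths) - 1)) {
    fine <- parts[[i]]; coarse <- parts[[i + 1]]
    # every fine cluster maps into exactly one coarse cluster
    expect_true(all(tapply(coarse, fine,
                           function(v) length(unique(v))) == 1L),
                info = sprintf("t=%g vs t=%g", ths[i], ths[i + 1]))
  }
})

test_that("the 2.2% threshold recovers well-separated simulated species", {
  sim <- simulateReferenceLibrary(simConfig(nSpecies = 10, seed = 4))
  d <- k2pMatrix(sim$library)
  expect_true(samePartition(slcCluster(d, 0.022), sim$truth@molecular))
})

test_that("silhouette refinement splits a planted deep component", {
  ids <- sprintf("s%02d", 1:8)
  d <- matrix(0.09, 8, 8, dimnames = list(ids, ids))  # two blocks at 9%
  d[1:4, 1:4] <- 0.004
  d[5:8, 5:8] <- 0.004
  diag(d) <- 0
  # threshold above the block separation: one component, refined in two
  refined <- slcCluster(d, threshold = 0.1, refine = TRUE)
  expect_equal(motuCount(refined), 2L)
  plain <- slcCluster(d, threshold = 0.1, refine = FALSE)
  expect_equal(motuCount(plain), 1L)
})

# ASAP-style hierarchical partitioning ----------------------------------

test_that("ASAP scoring always carries the trivial partitions", {
  sim <- simulateReferenceLibrary(simConfig(nSpecies = 5, seed = 6))
  d <- k2pMatrix(sim$library)
  res <- asapPartitions(d)
  expect_true(any(res@candidates$k == 1L))
  expect_true(any(res@candidates$k == nrow(d)))
  expect_true(all(res@candidates$asap_score >= 1))
  # nestedness of the single-linkage candidates as threshold grows
  cand <- res@candidates
  ordT <- order(cand$threshold)
  labsOrd <- res@partitions[ordT]
  for (i in seq_len(length(labsOrd) - 1)) {
    fine <- labsOrd[[i]]; coarse <- labsOrd[[i + 1]]
    expect_true(all(tapply(coarse, fine,
                           function(v) length(unique(v))) == 1L))
  }
})

test_that("identical sequences collapse to a single ASAP candidate", {
  seqs <- setNames(rep(paste(rep("ACGT", 25), collapse = ""), 4),
                   paste0("s", 1:4))
  md <- data.frame(sequence_id = names(seqs), species = "S", genus = "G",
                   family = "F", order = "O", source = "trawl", site = "x")
  d <- k2pMatrix(referenceLibrary(seqs, md))
  expect_warning(res <- asapPartitions(d), "equal")
  expect_equal(res@best@k, 1L)
})

test_that("ASAP top choice equals truth on wide-gap libraries", {
  # narrow within-species diversity against a >= 5% barcode gap
  hits <- 0L
  for (s in 1:100) {
    cfg <- simConfig(nSpecies = 10, theta = 0.002, seed = s)
    sim <- simulateReferenceLibrary(cfg)
    res <- asapPartitions(k2pMatrix(sim$library))
    if (samePartition(res@best, sim$truth@molecular)) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

# Poisson tree processes -------------------------------------------------

test_that("PTP separates classes at a 100-fold rate contrast", {
  set.seed(31)
  aris <- replicate(50, {
    sp <- ape::rtree(8)
    sp$edge.length <- rexp(nrow(sp$edge), rate = 1)
    tree <- sp
    truth <- character(0)
    for (tip in sp$tip.label) {
      sub <- ape::rtree(4)
      sub$edge.length <- rexp(nrow(sub$edge), rate = 100)
      sub$tip.label <- paste(tip, 1:4, sep = "_")
      w <- match(tip, tree$tip.label)
      tree <- ape::bind.tree(tree, sub, where = w)
      truth <- c(truth, setNames(rep(tip, 4), sub$tip.label))
    }
    fit <- ptpFit(tree, mode = "single", seed = 1)
    ariOf(fit@partition, truth)
  })
  expect_gte(median(aris), 0.9)
})

test_that("a zero-length cherry stays in one MOTU", {
  tree <- ape::read.tree(
    text = "((a:0,b:0):0.5,(c:0.4,(d:0.01,e:0.012):0.4):0.1);")
  fit <- ptpFit(tree, seed = 3)
  a <- motuAssignments(fit@partition)
  expect_equal(a[["a"]], a[["b"]])
})

test_that("a star tree yields a single MOTU with a warning", {
  tree <- ape::read.tree(text = "(a:0.1,b:0.2,c:0.15,d:0.3);")
  expect_warning(fit <- ptpFit(tree, seed = 1), "star")
  expect_equal(fit@partition@k, 1L)
})

test_that("PTP model bookkeeping is coherent", {
  sim <- simulateReferenceLibrary(simConfig(nSpecies = 8, seed = 15))
  d <- k2pMatrix(sim$library)
  fit <- ptpFit(njTree(d), seed = 2)
  expect_gte(fit@logL, fit@nullLogL)
  expect_true(fit@pValue > 0 && fit@pValue <= 1)
  expect_true(is.finite(fit@aic))
  expect_setequal(names(motuAssignments(fit@partition)), seqIds(sim$library))
})

# GMYC ------------------------------------------------------------------

test_that("GMYC model selection maximises the scanned likelihood", {
  sim <- simulateReferenceLibrary(simConfig(nSpecies = 8, seed = 17))
  d <- k2pMatrix(sim$library)
  fit <- gmycFit(upgmaTree(d), seed = 1)
  scan <- fit@details$scan
  expect_equal(fit@logL, max(scan$logL), tolerance = 1e-9)
  expect_gte(fit@logL, fit@nullLogL)
  expect_equal(fit@lrStat,
               max(0, 2 * (fit@logL - fit@nullLogL)), tolerance = 1e-9)
  # the scan covers the whole range of cluster counts
  expect_equal(min(scan$k), 1)
})

test_that("GMYC likelihood agrees with a brute-force recomputation", {
  set.seed(23)
  for (i in 1:4) {
    sim <- simulateReferenceLibrary(
      simConfig(nSpecies = 6, seqsMax = 6, seed = 40 + i))
    tree <- sim$truth@genealogy      # continuous heights, tie-free
    fit <- gmycFit(tree, seed = 1)
    if (length(fit@threshold) != 1) next
    naive <- naiveGmycLogL(tree, fit@threshold, fit@lambdaYule,
                           fit@pYule, fit@lambdaCoal, fit@pCoal)
    expect_equal(fit@logL, naive, tolerance = 1e-6)
  }
})

test_that("GMYC degenerate inputs are handled explicitly", {
  two <- ape::read.tree(text = "(a:1,b:1);")
  expect_warning(fit <- gmycFit(two, seed = 1), "two-leaf")
  expect_equal(fit@partition@k, 1L)

  bad <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:2.5):1);")
  expect_error(gmycFit(bad, seed = 1), "not ultrametric.*d")

  multi <- ape::read.tree(text = "((a:1,b:1,c:1):1,d:2);")
  expect_error(gmycFit(multi, seed = 1), "binary")
})

test_that("GMYC delimits simulated species on the true genealogy", {
  aris <- vapply(1:10, function(s) {
    sim <- simulateReferenceLibrary(simConfig(nSpecies = 10, seed = 50 + s))
    fit <- gmycFit(sim$truth@genealogy, seed = 1)
    ariOf(fit@partition, sim$truth@molecular)
  }, numeric(1))
  expect_gte(median(aris), 0.9)
})
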