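# General mixed Yule-coalescent delimitation on an ultrametric tree.
#
# Candidate single-threshold models place a height T between consecutive
# branching-event levels: nodes older than T are diversification (Yule)
# events, nodes at or below T are within-species coalescent events, and
# species are the subtrees hanging below T. Inter-event waiting times
# x_i with lineage counts per class give the likelihood
#   prod_events r(event) * prod_i exp(-b_i x_i),
#   b_i = lambda_y (n_y^p_y - 1) + lambda_c sum_k n_k (n_k - 1)^p_c,
# with each event's factor taken from its class and its level's lineage
# counts. The single-coalescent null (T above the root) is always
# scanned, so the fitted maximum is never below the null.
#
# Two guards keep the likelihood proper on distance-derived (UPGMA)
# trees: clades of identical leaves (zero-height nodes) are collapsed to
# one representative before fitting and re-expanded afterwards - a
# zero-length coalescence has unbounded density under any continuous
# model; and nodes at exactly tied heights are merged into one event
# level (treated as simultaneous events) instead of being jittered
# apart, which keeps the scan deterministic and leaves no
# infinitesimal interval for a runaway rate estimate to exploit.

.gmycPrep <- function(tree) {
  nTip <- length(tree$tip.label)
  h <- .nodeHeights(tree)
  h[seq_len(nTip)] <- 0
  internal <- (nTip + 1L):(nTip + tree$Nnode)
  H <- max(h)
  tol <- H * 1e-9
  # group tied internal heights into event levels (oldest level first)
  hi <- sort(unique(h[internal]), decreasing = TRUE)
  lev <- c(1L, cumsum(diff(hi) < -tol) + 1L)
  tOld <- vapply(split(hi, lev), max, numeric(1))
  nodeLevel <- integer(nTip + tree$Nnode)
  for (v in internal)
    nodeLevel[v] <- which(tOld - h[v] < tol & tOld - h[v] > -tol)[1]
  h[internal] <- tOld[nodeLevel[internal]]      # snap to level heights
  nLev <- length(tOld)
  x <- tOld - c(tOld[-1], 0)
  parent <- integer(nTip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  children <- vector("list", nTip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge)))
    children[[tree$edge[e, 1]]] <-
      c(children[[tree$edge[e, 1]]], tree$edge[e, 2])
  childNode <- tree$edge[, 2]
  eps <- min(x[x > tol], H) / 2
  crossing <- matrix(FALSE, nrow(tree$edge), nLev)
  for (e in seq_len(nrow(tree$edge))) {
    hc <- h[childNode[e]]; hp <- h[parent[childNode[e]]]
    crossing[e, ] <- hc < tOld - eps & hp > tOld - eps
  }
  evNodes <- internal[order(nodeLevel[internal])]
  list(tree = tree, nTip = nTip, h = h, tOld = tOld, x = x, nLev = nLev,
       nodeLevel = nodeLevel, evNodes = evNodes, parent = parent,
       children = children, childNode = childNode, crossing = crossing,
       root = nTip + 1L)
}

# Cluster structure for a Yule-node set (logical over all nodes).
.gmycStructure <- function(prep, isYule) {
  nTip <- prep$nTip
  nNode <- length(prep$parent)
  clusterOf <- integer(nNode)          # 0 for Yule nodes
  for (v in .preorder(prep$children, prep$root)) {
    p <- prep$parent[v]
    if (p == 0L) {                     # root
      clusterOf[v] <- if (isYule[v]) 0L else v
    } else if (clusterOf[p] != 0L) {
      clusterOf[v] <- clusterOf[p]
    } else {
      clusterOf[v] <- if (v <= nTip || !isYule[v]) v else 0L
    }
  }
  edgeClass <- clusterOf[prep$parent[prep$childNode]]  # 0 = Yule lineage
  roots <- sort(unique(clusterOf[clusterOf != 0L]))
  counts <- rowsum(prep$crossing + 0L, group = edgeClass)
  grp <- as.integer(rownames(counts))
  nY <- if (0L %in% grp) counts[match(0L, grp), ]
        else numeric(prep$nLev)
  Cmat <- matrix(0, length(roots), prep$nLev)
  hit <- match(roots, grp)
  Cmat[!is.na(hit), ] <- counts[hit[!is.na(hit)], , drop = FALSE]
  list(isYule = isYule, clusterOf = clusterOf, roots = roots, nY = nY,
       Cmat = Cmat,
       evLevel = prep$nodeLevel[prep$evNodes],
       evYule = isYule[prep$evNodes],
       evCluster = match(clusterOf[prep$evNodes], roots))
}

.gmycLogL <- function(par, st, x, hasY, hasC) {
  ly <- if (hasY) exp(par[["ay"]]) else 0
  py <- if (hasY) par[["py"]] else 1
  lc <- if (hasC) exp(par[["ac"]]) else 0
  pc <- if (hasC) par[["pc"]] else 1
  yuleTerm <- ifelse(st$nY >= 1, st$nY^py - 1, 0)
  Cm <- st$Cmat
  coalTerm <- if (nrow(Cm)) colSums(Cm * ifelse(Cm > 1, (Cm - 1)^pc, 0))
              else numeric(length(x))
  b <- ly * yuleTerm + lc * coalTerm
  # each event level contributes the waiting-time density b e^(-b x)
  # with the total branching rate of its interval
  r <- b[st$evLevel]
  if (any(r <= 0)) return(-Inf)
  sum(log(r)) - sum(b * x)
}

.gmycFitSet <- function(prep, isYule, init = NULL) {
  st <- .gmycStructure(prep, isYule)
  hasY <- any(st$evYule)
  hasC <- any(!st$evYule)
  start <- c(ay = 0, py = 1, ac = 0, pc = 1)
  yTerm <- ifelse(st$nY >= 1, st$nY - 1, 0)
  cTerm <- if (nrow(st$Cmat))
    colSums(st$Cmat * pmax(st$Cmat - 1, 0)) else 0
  if (hasY) {
    denom <- sum(yTerm * prep$x)
    start[["ay"]] <- log(max(sum(st$evYule) / max(denom, 1e-12), 1e-6))
  }
  if (hasC) {
    denom <- sum(cTerm * prep$x)
    start[["ac"]] <- log(max(sum(!st$evYule) / max(denom, 1e-12), 1e-6))
  }
  if (!is.null(init)) start[names(init)] <- init
  free <- c(if (hasY) c("ay", "py"), if (hasC) c("ac", "pc"))
  x <- prep$x
  Y <- st$nY
  yPos <- Y >= 1
  Cm <- st$Cmat
  cPos <- Cm > 1
  logCm1 <- ifelse(cPos, log(pmax(Cm - 1, 1)), 0)
  ev <- st$evLevel
  cache <- new.env(parent = emptyenv())
  evaluate <- function(v) {
    par <- start
    par[free] <- v
    ly <- if (hasY) exp(par[["ay"]]) else 0
    py <- par[["py"]]
    lc <- if (hasC) exp(par[["ac"]]) else 0
    pc <- par[["pc"]]
    yuleTerm <- ifelse(yPos, Y^py - 1, 0)
    CmP <- ifelse(cPos, (Cm - 1)^pc, 0)
    coalTerm <- if (nrow(Cm)) colSums(Cm * CmP) else numeric(length(x))
    b <- ly * yuleTerm + lc * coalTerm
    r <- b[ev]
    if (any(r <= 0) || any(!is.finite(b))) {
      cache$value <- 1e10
      cache$grad <- rep(0, length(free))
      return(invisible(NULL))
    }
    value <- sum(log(r)) - sum(b * x)
    # d(-logL)/d(theta) with db/dtheta per interval
    gOf <- function(db) -(sum(db[ev] / r) - sum(db * x))
    g <- c(ay = if (hasY) gOf(ly * yuleTerm),
           py = if (hasY) gOf(ly * ifelse(yPos, Y^py * log(pmax(Y, 1)), 0)),
           ac = if (hasC) gOf(lc * coalTerm),
           pc = if (hasC) gOf(lc * (if (nrow(Cm))
             colSums(Cm * CmP * logCm1) else numeric(length(x)))))
    cache$value <- -value
    cache$grad <- g[free]
    invisible(NULL)
  }
  fn <- function(v) {
    if (is.null(cache$par) || !identical(v, cache$par)) {
      cache$par <- v
      evaluate(v)
    }
    cache$value
  }
  gr <- function(v) {
    if (is.null(cache$par) || !identical(v, cache$par)) {
      cache$par <- v
      evaluate(v)
    }
    cache$grad
  }
  lower <- c(ay = -25, py = 0.01, ac = -25, pc = 0.01)[free]
  upper <- c(ay = 25, py = 3, ac = 25, pc = 3)[free]
  opt <- stats::optim(start[free], fn, gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 200, factr = 1e9))
  par <- start
  par[free] <- opt$par
  list(logL = -opt$value, par = par, k = length(st$roots), st = st,
       hasY = hasY, hasC = hasC)
}

.gmycClustersToLabels <- function(prep, st) {
  lab <- st$clusterOf[seq_len(prep$nTip)]
  stats::setNames(lab, prep$tree$tip.label)
}

# collapse clades of (effectively) identical leaves to one representative
.collapseZeroClades <- function(tree) {
  h <- .nodeHeights(tree)
  nTip <- length(tree$tip.label)
  h[seq_len(nTip)] <- 0
  zeroTol <- max(h) * 1e-6
  parent <- integer(length(h))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  zero <- which(h < zeroTol)
  zero <- zero[zero > nTip]
  rep <- stats::setNames(tree$tip.label, tree$tip.label)
  if (!length(zero)) return(list(tree = tree, map = rep))
  maximal <- zero[h[parent[zero]] >= zeroTol | parent[zero] == 0L]
  drop <- character(0)
  for (v in maximal) {
    tips <- ape::extract.clade(tree, v)$tip.label
    rep[tips] <- tips[1]
    drop <- c(drop, tips[-1])
  }
  list(tree = ape::drop.tip(tree, drop), map = rep)
}

.gmycNullTree <- function(n, lambda, p) {
  m <- n:2
  times <- cumsum(stats::rexp(length(m), rate = lambda * (m * (m - 1))^p))
  nwk <- as.list(paste0("t", seq_len(n)))
  hgt <- rep(0, n)
  for (i in seq_along(m)) {
    pick <- sample.int(length(nwk), 2)
    hNew <- times[i]
    nw <- sprintf("(%s:%.12g,%s:%.12g)",
                  nwk[[pick[1]]], hNew - hgt[pick[1]],
                  nwk[[pick[2]]], hNew - hgt[pick[2]])
    nwk <- c(nwk[-pick], nw)
    hgt <- c(hgt[-pick], hNew)
  }
  ape::read.tree(text = paste0(nwk[[1]], ";"))
}

.gmycScan <- function(prep) {
  nLev <- prep$nLev
  nNode <- length(prep$parent)
  fits <- vector("list", nLev + 1L)   # j = 0..nLev oldest levels are Yule
  init <- NULL
  for (j in 0:nLev) {
    isYule <- logical(nNode)
    if (j > 0) isYule[prep$evNodes[prep$nodeLevel[prep$evNodes] <= j]] <- TRUE
    fits[[j + 1L]] <- .gmycFitSet(prep, isYule, init = init)
    fits[[j + 1L]]$j <- j
    fits[[j + 1L]]$isYule <- isYule
    init <- fits[[j + 1L]]$par
  }
  fits
}

#' General mixed Yule-coalescent (GMYC) species delimitation
#'
#' Scans every between-level threshold height on a rooted, binary,
#' ultrametric tree (the single-coalescent null, threshold above the
#' root, included), fitting diversification and coalescent rate/exponent
#' parameters at each by maximum likelihood. The fitted model is the
#' scan's maximum; the likelihood-ratio test against the null uses a
#' chi-square mixture (equal weights on 2 and 3 degrees of freedom) or,
#' optionally, a parametric bootstrap that re-simulates single-population
#' coalescent trees from the fitted null. When the null is not rejected
#' at \code{alpha} the returned partition has k = 1. Multiple-threshold
#' mode greedily promotes cluster roots to diversification nodes while
#' AIC (one extra parameter per added threshold) improves.
#'
#' Clades of identical leaves are collapsed to a single representative
#' before fitting (and re-expanded in the returned partition), and
#' exactly tied node heights are merged into one simultaneous event
#' level; both are required for a proper likelihood on distance-derived
#' ultrametric trees.
#'
#' @param tree Rooted, binary, ultrametric \code{phylo} (checked; the
#'   error names the worst-deviating leaf).
#' @param mode \code{"single"} or \code{"multiple"} threshold(s).
#' @param test \code{"lrt"} (default) or \code{"bootstrap"}. The LRT's
#'   chi-square mixture reference ignores that the threshold is chosen
#'   by maximisation over all candidate heights, so it runs mildly
#'   anticonservative; the parametric bootstrap
#'   re-simulates single-population coalescent trees from the fitted
#'   null and re-runs the full scan on each, so it is calibrated by
#'   construction and is the choice when type-I control matters. It
#'   costs \code{nBoot} extra scans.
#' @param nBoot Bootstrap replicates when \code{test = "bootstrap"}.
#' @param alpha Rejection level.
#' @param seed Seed (used by the bootstrap test only; the scan itself is
#'   deterministic).
#' @return A [GMYCModel-class]; \code{@details$scan} holds the
#'   per-candidate table (threshold, k, logL).
#' @export
gmycFit <- function(tree, mode = c("single", "multiple"),
                    test = c("lrt", "bootstrap"), nBoot = 99,
                    alpha = 0.05, seed = 0L) {
  mode <- match.arg(mode)
  test <- match.arg(test)
  if (!ape::is.rooted(tree)) stop("GMYC requires a rooted tree")
  nTip <- length(tree$tip.label)
  trivial <- function(msg) {
    warning(msg)
    part <- motuPartition(if (mode == "multiple") "mGMYC" else "GMYC",
                          stats::setNames(rep("GMYC_001", nTip),
                                          tree$tip.label))
    methods::new("GMYCModel", partition = part, threshold = numeric(0),
                 lambdaYule = NA_real_, pYule = NA_real_,
                 lambdaCoal = NA_real_, pCoal = NA_real_, logL = NA_real_,
                 nullLogL = NA_real_, lrStat = 0, pValue = 1,
                 mode = mode, details = list())
  }
  if (nTip == 2L)
    return(trivial("two-leaf tree: threshold undefined, returning k = 1"))
  if (!ape::is.binary.phylo(tree))
    stop("GMYC requires a fully resolved (binary) tree")
  ultra <- isUltrametric(tree, tol = 1e-6 * max(.nodeHeights(tree)))
  if (!ultra)
    stop(sprintf("tree is not ultrametric: leaf '%s' deviates by %g",
                 attr(ultra, "worst_leaf"), attr(ultra, "deviation")))
  collapsed <- .collapseZeroClades(tree)
  work <- collapsed$tree
  if (length(work$tip.label) < 3L)
    return(trivial("fewer than 3 distinct haplotypes: returning k = 1"))
  prep <- .gmycPrep(work)
  fits <- .gmycScan(prep)
  logLs <- vapply(fits, `[[`, numeric(1), "logL")
  nullFit <- fits[[1L]]
  scan <- data.frame(
    n_yule_levels = 0:prep$nLev,
    threshold = c(Inf, (prep$tOld + c(prep$tOld[-1], 0)) / 2),
    k = vapply(fits, `[[`, numeric(1), "k"),
    logL = logLs)
  fit <- fits[[which.max(logLs)]]
  thresholds <- if (fit$j == 0) numeric(0) else scan$threshold[fit$j + 1L]
  nParExtra <- 1L
  if (mode == "multiple") {
    # greedily give individual clusters their own, deeper threshold
    repeat {
      rootsInt <- fit$st$roots[fit$st$roots > prep$nTip]
      if (!length(rootsInt)) break
      cand <- lapply(rootsInt, function(r) {
        isY <- fit$isYule
        isY[r] <- TRUE
        f <- .gmycFitSet(prep, isY, init = fit$par)
        f$isYule <- isY
        f$j <- fit$j
        f
      })
      lls <- vapply(cand, `[[`, numeric(1), "logL")
      b <- which.max(lls)
      if (2 * (lls[b] - fit$logL) > 2) {  # AIC gain for +1 threshold
        fit <- cand[[b]]
        thresholds <- c(thresholds, prep$h[rootsInt[b]])
        nParExtra <- nParExtra + 1L
      } else break
    }
  }
  lr <- max(0, 2 * (fit$logL - nullFit$logL))
  if (test == "lrt") {
    pValue <- if (lr == 0) 1 else
      0.5 * (1 - stats::pchisq(lr, 2)) + 0.5 * (1 - stats::pchisq(lr, 3))
  } else {
    set.seed(seed + 1L)
    lambda0 <- exp(nullFit$par[["ac"]])
    p0 <- nullFit$par[["pc"]]
    lrStar <- vapply(seq_len(nBoot), function(b) {
      bp <- .gmycPrep(.gmycNullTree(length(work$tip.label), lambda0, p0))
      ll <- vapply(.gmycScan(bp), `[[`, numeric(1), "logL")
      max(0, 2 * (max(ll) - ll[1]))
    }, numeric(1))
    pValue <- (1 + sum(lrStar >= lr - 1e-9)) / (nBoot + 1)
  }
  reject <- pValue < alpha
  chosen <- if (reject) fit else nullFit
  lab <- .gmycClustersToLabels(prep, chosen$st)
  lab <- lab[collapsed$map]                       # re-expand haplotypes
  names(lab) <- names(collapsed$map)
  methodLab <- if (mode == "multiple") "mGMYC" else "GMYC"
  part <- motuPartition(methodLab,
                        .labelByFirst(lab[tree$tip.label], tree$tip.label,
                                      methodLab))
  methods::new("GMYCModel", partition = part,
               threshold = if (reject) thresholds else numeric(0),
               lambdaYule = if (fit$hasY) exp(fit$par[["ay"]]) else NA_real_,
               pYule = if (fit$hasY) fit$par[["py"]] else NA_real_,
               lambdaCoal = if (fit$hasC) exp(fit$par[["ac"]]) else NA_real_,
               pCoal = if (fit$hasC) fit$par[["pc"]] else NA_real_,
               logL = fit$logL, nullLogL = nullFit$logL, lrStat = lr,
               pValue = pValue, mode = mode,
               details = list(scan = scan, n_par_thresholds = nParExtra,
                              n_haplotypes = length(work$tip.label)))
}
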