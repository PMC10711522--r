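# Poisson tree process delimitation.
#
# A delimitation is a set of "crown" nodes (possibly tips): every tip has
# exactly one ancestor-or-self in the set. Edges strictly below a crown
# are within-species (coalescent-class) events; all other edges are
# speciation-class. Each class contributes an exponential likelihood with
# its maximum-likelihood rate; multi-rate mode gives each multi-sequence
# species its own within-species rate.

.ptpPrep <- function(tree, minBr = 1e-4) {
  nTip <- length(tree$tip.label)
  nNode <- nTip + tree$Nnode
  children <- vector("list", nNode)
  for (e in seq_len(nrow(tree$edge)))
    children[[tree$edge[e, 1]]] <-
      c(children[[tree$edge[e, 1]]], tree$edge[e, 2])
  edgeLen <- numeric(nNode)  # length of the edge above each node
  edgeLen[tree$edge[, 2]] <- pmax(tree$edge.length, 1e-8)
  # branches below the resolution floor carry no information about
  # branching rates (identical haplotypes) and would let a rate estimate
  # diverge; they are excluded from both classes, as is standard for
  # tree-process delimitation
  counted <- edgeLen >= minBr
  root <- nTip + 1L
  nBelow <- integer(nNode)
  sumBelow <- numeric(nNode)
  # postorder accumulation over counted edges only
  ord <- rev(.preorder(children, root))
  for (v in ord) {
    ch <- children[[v]]
    if (length(ch)) {
      nBelow[v] <- sum(counted[ch] + nBelow[ch])
      sumBelow[v] <- sum(edgeLen[ch] * counted[ch] + sumBelow[ch])
    }
  }
  list(nTip = nTip, root = root, children = children, edgeLen = edgeLen,
       nBelow = nBelow, sumBelow = sumBelow,
       nEdges = sum(counted[tree$edge[, 2]]),
       lenTotal = sum(edgeLen[tree$edge[, 2]][counted[tree$edge[, 2]]]),
       parent = {p <- integer(nNode); p[tree$edge[, 2]] <- tree$edge[, 1]; p},
       tipLabels = tree$tip.label)
}

.preorder <- function(children, root) {
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, children[[v]])
  }
  out
}

.expLogL <- function(n, L) if (n == 0L) 0 else n * log(n / L) - n

.ptpLogL <- function(prep, S, mode) {
  nCo <- sum(prep$nBelow[S])
  LCo <- sum(prep$sumBelow[S])
  nSp <- prep$nEdges - nCo
  LSp <- prep$lenTotal - LCo
  ll <- .expLogL(nSp, LSp)
  if (mode == "single") {
    ll + .expLogL(nCo, LCo)
  } else {
    act <- S[prep$nBelow[S] > 0L]
    ll + sum(vapply(act, function(v)
      .expLogL(prep$nBelow[v], prep$sumBelow[v]), numeric(1)))
  }
}

.ptpMoves <- function(prep, S) {
  splits <- S[S > prep$nTip]  # internal crowns can expand to children
  inS <- logical(length(prep$parent)); inS[S] <- TRUE
  par <- unique(prep$parent[S])
  par <- par[par != 0L]
  merges <- par[vapply(par, function(p)
    all(inS[prep$children[[p]]]), logical(1))]
  list(splits = splits, merges = merges)
}

.ptpApply <- function(prep, S, move, type) {
  if (type == "split") c(setdiff(S, move), prep$children[[move]])
  else c(setdiff(S, prep$children[[move]]), move)
}

.ptpGreedy <- function(prep, S, mode) {
  ll <- .ptpLogL(prep, S, mode)
  repeat {
    mv <- .ptpMoves(prep, S)
    cand <- c(lapply(mv$splits, function(v) list(v = v, type = "split")),
              lapply(mv$merges, function(v) list(v = v, type = "merge")))
    if (!length(cand)) break
    lls <- vapply(cand, function(cc)
      .ptpLogL(prep, .ptpApply(prep, S, cc$v, cc$type), mode), numeric(1))
    b <- which.max(lls)
    if (lls[b] <= ll + 1e-9) break
    S <- .ptpApply(prep, S, cand[[b]]$v, cand[[b]]$type)
    ll <- lls[b]
  }
  list(S = S, logL = ll)
}

.ptpRandomStart <- function(prep) {
  S <- integer(0)
  stack <- prep$root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= prep$nTip || stats::runif(1) > 0.5) S <- c(S, v)
    else stack <- c(stack, prep$children[[v]])
  }
  S
}

.ptpSearch <- function(prep, mode, nRestarts, annealIters = 200) {
  best <- .ptpGreedy(prep, prep$root, mode)
  for (r in seq_len(nRestarts)) {
    S <- .ptpRandomStart(prep)
    ll <- .ptpLogL(prep, S, mode)
    temp <- 1
    cool <- 0.01^(1 / max(annealIters - 1, 1))
    for (it in seq_len(annealIters)) {
      mv <- .ptpMoves(prep, S)
      pool <- c(lapply(mv$splits, function(v) list(v = v, type = "split")),
                lapply(mv$merges, function(v) list(v = v, type = "merge")))
      if (!length(pool)) break
      cc <- pool[[sample.int(length(pool), 1)]]
      S2 <- .ptpApply(prep, S, cc$v, cc$type)
      ll2 <- .ptpLogL(prep, S2, mode)
      if (ll2 > ll || stats::runif(1) < exp((ll2 - ll) / temp)) {
        S <- S2; ll <- ll2
      }
      temp <- temp * cool
    }
    polished <- .ptpGreedy(prep, S, mode)
    if (polished$logL > best$logL) best <- polished
  }
  best
}

.ptpPartitionFromS <- function(prep, S) {
  lab <- integer(prep$nTip)
  for (i in seq_along(S)) {
    sub <- .preorder(prep$children, S[i])
    tips <- sub[sub <= prep$nTip]
    lab[tips] <- i
  }
  stats::setNames(lab, prep$tipLabels)
}

#' Poisson tree process (PTP) species delimitation
#'
#' Classifies the branches of a metric (substitutions/site) tree into
#' speciation- and coalescent-class events, each modelled with an
#' exponential rate (multi-rate mode: one within-species rate per
#' multi-sequence MOTU). The boundary set is found by greedy
#' edge-flipping from the single-species root partition plus
#' simulated-annealing restarts. Significance against the one-rate null
#' (all branches from a single exponential) is assessed by a parametric
#' bootstrap: branch lengths are redrawn i.i.d. from the fitted null
#' exponential on the same topology and the search is re-run, giving the
#' null distribution of the log-likelihood improvement. When the null is
#' not rejected at \code{alpha}, the returned partition has k = 1.
#'
#' @param tree A metric \code{phylo} with at least 4 leaves; unrooted
#'   trees are midpoint-rooted. Zero-length branches are perturbed to
#'   1e-8.
#' @param mode \code{"single"} (one shared within-species rate),
#'   \code{"multi"} (one per species), or \code{"auto"} (default): both
#'   searches are run and the model with the lower AIC (rates plus
#'   boundary nodes as parameters) is kept.
#' @param nRestarts Simulated-annealing restarts (default 10).
#' @param seed Integer seed for the stochastic search (required).
#' @param nBoot Parametric-bootstrap replicates for the null test.
#' @param alpha Rejection level for the null test.
#' @param minBr Minimum informative branch length; shorter branches
#'   (identical haplotypes) are excluded from both rate classes.
#' @return A [PTPModel-class].
#' @export
ptpFit <- function(tree, mode = c("auto", "single", "multi"),
                   nRestarts = 10, seed, nBoot = 20, alpha = 0.05,
                   minBr = 1e-4) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("an integer seed is required")
  set.seed(seed)
  if (length(tree$tip.label) < 4L)
    stop("PTP needs a tree with at least 4 leaves")
  if (tree$Nnode == 1L) {
    warning("star tree: no boundary structure to estimate; returning k = 1")
    prep <- .ptpPrep(ape::multi2di(tree), minBr = minBr)
    nullLogL <- .ptpLogL(prep, prep$root, "single")
    part <- motuPartition(if (mode == "multi") "mPTP" else "PTP",
                          stats::setNames(rep("PTP_001",
                                              length(tree$tip.label)),
                                          tree$tip.label))
    return(methods::new("PTPModel", partition = part,
                        lambdaSp = NA_real_,
                        lambdaCoal = prep$nEdges / prep$lenTotal,
                        logL = nullLogL, nullLogL = nullLogL, pValue = 1,
                        aic = 2 * 2 - 2 * nullLogL, mode = mode))
  }
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  prep <- .ptpPrep(tree, minBr = minBr)
  if (prep$nEdges < 2L)
    stop("tree has fewer than 2 branches above the resolution floor")
  nullLogL <- .ptpLogL(prep, prep$root, "single")
  aicOf <- function(fit, m) {
    nRates <- 1L + if (m == "single") 1L else sum(prep$nBelow[fit$S] > 0L)
    2 * (nRates + length(fit$S)) - 2 * fit$logL
  }
  if (mode == "auto") {
    fits <- lapply(c("single", "multi"), function(m)
      .ptpSearch(prep, m, nRestarts))
    aics <- c(aicOf(fits[[1]], "single"), aicOf(fits[[2]], "multi"))
    mode <- c("single", "multi")[which.min(aics)]
    best <- fits[[which.min(aics)]]
  } else {
    best <- .ptpSearch(prep, mode, nRestarts)
  }
  delta <- best$logL - nullLogL
  nullRate <- prep$nEdges / prep$lenTotal
  exceed <- 0L
  for (b in seq_len(nBoot)) {
    bootTree <- tree
    bootTree$edge.length <- stats::rexp(nrow(tree$edge), rate = nullRate)
    bootPrep <- .ptpPrep(bootTree, minBr = minBr)
    bb <- .ptpSearch(bootPrep, mode, nRestarts)
    if (bb$logL - .ptpLogL(bootPrep, bootPrep$root, "single") >=
        delta - 1e-9) exceed <- exceed + 1L
  }
  pValue <- (1 + exceed) / (nBoot + 1)
  S <- if (pValue < alpha) best$S else prep$root
  lab <- .ptpPartitionFromS(prep, S)
  part <- motuPartition(if (mode == "multi") "mPTP" else "PTP",
                        .labelByFirst(lab, prep$tipLabels,
                                      if (mode == "multi") "mPTP" else "PTP"))
  nCo <- sum(prep$nBelow[best$S]); LCo <- sum(prep$sumBelow[best$S])
  nSp <- prep$nEdges - nCo; LSp <- prep$lenTotal - LCo
  lambdaSp <- if (nSp > 0) nSp / LSp else NA_real_
  lambdaCoal <- if (mode == "single") {
    if (nCo > 0) nCo / LCo else NA_real_
  } else {
    act <- best$S[prep$nBelow[best$S] > 0L]
    stats::setNames(prep$nBelow[act] / prep$sumBelow[act],
                    vapply(act, function(v) {
                      sub <- .preorder(prep$children, v)
                      prep$tipLabels[min(sub[sub <= prep$nTip])]
                    }, character(1)))
  }
  methods::new("PTPModel", partition = part, lambdaSp = lambdaSp,
               lambdaCoal = lambdaCoal, logL = best$logL,
               nullLogL = nullLogL, pValue = pValue,
               aic = aicOf(best, mode), mode = mode)
}
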