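#' Sequence accumulation curve with permutation confidence band
#'
#' Classic sample-order randomisation: for each permutation of the
#' sequence order, the cumulative number of distinct labels (species or
#' MOTUs) is recorded; the mean and the empirical 2.5/97.5 percentiles
#' per sampling depth form the curve and its 95% band. Permutations are
#' delegated to [vegan::specaccum()] (each sequence is one sampling
#' unit). A plateau statistic summarises the terminal slope: the mean
#' richness gained per sequence over the last 10% of the curve, with
#' \code{plateau = TRUE} when it falls below 0.01 labels/sequence - a
#' programmatic stand-in for the visual judgement usually applied to
#' such curves.
#'
#' @param labels Character/factor vector of labels, one per sequence
#'   (\code{NA} dropped with a warning).
#' @param nPermutations Number of random orderings (default 100).
#' @param seed Integer seed (required: curves are resampled).
#' @return data.frame with columns \code{x, mean, q2.5, q97.5} and
#'   attributes \code{plateau}, \code{slope}, \code{n_permutations},
#'   \code{seed}.
#' @export
accumulationCurve <- function(labels, nPermutations = 100, seed) {
  if (missing(seed)) stop("an integer seed is required")
  if (anyNA(labels)) {
    warning(sum(is.na(labels)), " unlabelled sequence(s) dropped")
    labels <- labels[!is.na(labels)]
  }
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 1L) stop("at least one labelled sequence is required")
  set.seed(seed)
  uniq <- unique(labels)
  if (n == 1L || length(uniq) == 1L) {
    # degenerate cases: every ordering gives the same curve
    perm <- matrix(cummax(as.integer(factor(labels, levels = uniq))),
                   nrow = n, ncol = 1)
    perm[] <- vapply(seq_len(n), function(i)
      length(unique(labels[seq_len(i)])), numeric(1))
  } else {
    comm <- table(seq_len(n), factor(labels, levels = uniq))
    sac <- vegan::specaccum(unclass(comm), method = "random",
                            permutations = nPermutations)
    perm <- sac$perm
  }
  meanR <- rowMeans(perm)
  q <- t(apply(perm, 1, stats::quantile, probs = c(0.025, 0.975),
               names = FALSE))
  out <- data.frame(x = seq_len(n), mean = meanR,
                    q2.5 = q[, 1], q97.5 = q[, 2])
  x0 <- min(n - 1L, as.integer(ceiling(0.9 * n)))
  slope <- if (n >= 2L) (meanR[n] - meanR[x0]) / (n - x0) else NA_real_
  attr(out, "plateau") <- if (is.na(slope)) NA else slope < 0.01
  attr(out, "slope") <- slope
  attr(out, "n_permutations") <- nPermutations
  attr(out, "seed") <- seed
  out
}
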