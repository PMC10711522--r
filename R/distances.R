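# Integer encoding: A=1 C=2 G=3 T=4; gaps, N and every other IUPAC
# ambiguity code are 0 and are excluded pairwise (treated as missing at
# the distance stage).
.encodeSeq <- function(s) {
  x <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  unname(c(A = 1L, C = 2L, G = 3L, T = 4L)[x])
}

.encodeLibrary <- function(library) {
  chr <- as.character(library@sequences)
  m <- matrix(0L, nrow = length(chr), ncol = alignmentLength(library),
              dimnames = list(names(chr), NULL))
  for (i in seq_along(chr)) {
    v <- .encodeSeq(chr[i])
    v[is.na(v)] <- 0L
    m[i, ] <- v
  }
  m
}

.pairCounts <- function(a, b) {
  ok <- a > 0L & b > 0L
  m <- sum(ok)
  if (m == 0L) return(c(ts = 0L, tv = 0L, m = 0L))
  ai <- a[ok]; bi <- b[ok]
  diff <- ai != bi
  # transitions: both purine (A,G) or both pyrimidine (C,T)
  ts <- sum(diff & ((ai == 1L | ai == 3L) == (bi == 1L | bi == 3L)))
  c(ts = ts, tv = sum(diff) - ts, m = m)
}

#' Count transition/transversion site patterns between two aligned sequences
#'
#' Sites where either symbol is a gap, \code{N} or any other IUPAC
#' ambiguity code are excluded (pairwise deletion). Differences between
#' two purines (A/G) or two pyrimidines (C/T) are transitions; all other
#' differences are transversions.
#'
#' @param seqA,seqB Equal-length aligned sequences (character scalars).
#' @return A list with integer components \code{ts}, \code{tv} and
#'   \code{m} (jointly resolved sites).
#' @examples
#' countSitePatterns("ACGT", "GCGT")  # one A<->G transition over 4 sites
#' @export
countSitePatterns <- function(seqA, seqB) {
  if (nchar(seqA) != nchar(seqB))
    stop("sequences must have equal aligned length")
  a <- .encodeSeq(seqA); a[is.na(a)] <- 0L
  b <- .encodeSeq(seqB); b[is.na(b)] <- 0L
  as.list(.pairCounts(a, b))
}

#' Kimura 2-parameter distance from site-pattern counts
#'
#' Evaluates \eqn{d = -\frac{1}{2}\ln\big((1-2P-Q)\sqrt{1-2Q}\big)} with
#' \eqn{P = ts/m} and \eqn{Q = tv/m}. Outside the logarithm's domain
#' (saturation: \eqn{1-2P-Q \le 0} or \eqn{1-2Q \le 0}), or when
#' \eqn{m = 0}, the distance is undefined and \code{NA} is returned.
#' Vectorised over its arguments.
#'
#' @param ts,tv,m Transition, transversion and jointly-resolved-site
#'   counts, as from [countSitePatterns()].
#' @return Numeric vector of distances (substitutions/site), \code{NA}
#'   where undefined.
#' @examples
#' k2pFromCounts(1, 1, 10)  # P = Q = 0.1
#' @export
k2pFromCounts <- function(ts, tv, m) {
  P <- ts / m
  Q <- tv / m
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  d <- ifelse(m > 0 & a1 > 0 & a2 > 0,
              -0.5 * log(a1 * sqrt(a2)), NA_real_)
  d[m > 0 & ts == 0 & tv == 0] <- 0
  d
}

#' Pairwise K2P distance matrix for a library
#'
#' Computes all \eqn{n(n-1)/2} pairwise K2P distances under pairwise
#' deletion. Saturated or zero-overlap pairs yield \code{NA} cells, which
#' downstream summaries exclude (with a logged count) and tree builders
#' impute.
#'
#' @param library A [ReferenceLibrary-class].
#' @return A symmetric numeric matrix with zero diagonal, sequence ids as
#'   dimnames, and attributes \code{ts}, \code{tv}, \code{m} (integer
#'   matrices of the underlying counts) and \code{n_undefined} (count of
#'   undefined off-diagonal pairs, each pair counted once).
#' @export
k2pMatrix <- function(library) {
  codes <- .encodeLibrary(library)
  n <- nrow(codes)
  ids <- rownames(codes)
  resolved <- codes > 0L
  purine <- codes == 1L | codes == 3L
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  tsM <- tvM <- mM <- matrix(0L, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        ok <- resolved[i, ] & resolved[j, ]
        m <- sum(ok)
        if (m == 0L) { ts <- tv <- 0L } else {
          diff <- ok & (codes[i, ] != codes[j, ])
          ts <- sum(diff & (purine[i, ] == purine[j, ]))
          tv <- sum(diff) - ts
        }
        tsM[i, j] <- tsM[j, i] <- ts
        tvM[i, j] <- tvM[j, i] <- tv
        mM[i, j] <- mM[j, i] <- m
        d[i, j] <- d[j, i] <- k2pFromCounts(ts, tv, m)
      }
    }
  }
  structure(d, ts = tsM, tv = tvM, m = mM,
            n_undefined = sum(is.na(d[upper.tri(d)])))
}

#' @describeIn k2pMatrix Long-format lower-triangle table
#'   (\code{id_a, id_b, ts, tv, m, k2p}) for TSV export.
#' @param d A matrix from \code{k2pMatrix} (with count attributes).
#' @export
distanceTable <- function(d) {
  ids <- rownames(d)
  idx <- which(lower.tri(d), arr.ind = TRUE)
  data.frame(id_a = ids[idx[, 2]], id_b = ids[idx[, 1]],
             ts = attr(d, "ts")[idx], tv = attr(d, "tv")[idx],
             m = attr(d, "m")[idx], k2p = round(d[idx], 4),
             stringsAsFactors = FALSE)
}

#' Per-species barcode-gap records
#'
#' For every labelled species: the maximum conspecific (intraspecific)
#' distance, the nearest-neighbour distance (minimum over all pairs with
#' any other labelled species), the species attaining it, the
#' nearest-to-intra fold ratio, and whether a barcode gap is present
#' (\code{nn_dist > max_intra}). Unlabelled records are ignored.
#' Undefined (saturated) cells are excluded.
#'
#' @param d K2P matrix from [k2pMatrix()].
#' @param species Named character vector of species labels (\code{NA} for
#'   unidentified), names = sequence ids; e.g. [speciesLabels()].
#' @return data.frame with columns \code{species, n_seqs, max_intra,
#'   nn_dist, nn_taxon, fold, gap_present}. \code{max_intra} is \code{NA}
#'   for singletons; \code{fold} is \code{NA} unless \code{max_intra > 0};
#'   \code{gap_present} is \code{NA} when \code{max_intra} is undefined.
#' @export
speciesGapTable <- function(d, species) {
  species <- species[rownames(d)]
  lab <- !is.na(species)
  sp <- unique(species[lab])
  if (length(sp) < 2L)
    stop("at least two labelled species are required for nearest-neighbour ",
         "distances")
  out <- lapply(sp, function(s) {
    idx <- which(!is.na(species) & species == s)
    oth <- which(lab & species != s)
    maxIntra <- if (length(idx) >= 2L) {
      v <- d[idx, idx][upper.tri(diag(length(idx)))]
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    } else NA_real_
    het <- d[idx, oth, drop = FALSE]
    if (all(is.na(het))) {
      nn <- NA_real_; nnTaxon <- NA_character_
    } else {
      nn <- min(het, na.rm = TRUE)
      w <- which(het == nn, arr.ind = TRUE)[1, ]
      nnTaxon <- unname(species[oth[w[2]]])
    }
    data.frame(species = s, n_seqs = length(idx), max_intra = maxIntra,
               nn_dist = nn, nn_taxon = nnTaxon,
               fold = if (!is.na(maxIntra) && maxIntra > 0)
                 nn / maxIntra else NA_real_,
               gap_present = if (is.na(maxIntra)) NA else nn > maxIntra,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.pool <- function(d, maskUpper) d[maskUpper & upper.tri(d)]

.summarisePool <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v))
    return(data.frame(n_pairs = 0L, min = NA_real_, mean = NA_real_,
                      max = NA_real_, se = NA_real_))
  data.frame(n_pairs = length(v), min = min(v), mean = mean(v),
             max = max(v),
             se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0)
}

#' Rank-level summaries of pairwise K2P distances
#'
#' Pools pairwise distances at three mutually exclusive levels:
#' conspecific pairs (\code{within_species}), heterospecific congeneric
#' pairs (\code{within_genus}) and heterogeneric confamilial pairs
#' (\code{within_family}). Because published tables sometimes pool
#' inclusively (keeping lower-level pairs in the higher-level pools), an
#' inclusive variant is emitted side by side. Records lacking the labels
#' needed at a level are excluded from that level; \code{n_groups} counts
#' the distinct species/genera/families represented among labelled
#' records.
#'
#' @param d K2P matrix from [k2pMatrix()].
#' @param metadata Metadata table, e.g. [libraryMetadata()].
#' @return data.frame with columns \code{level, pooling, n_groups,
#'   n_pairs, min, mean, max, se}; levels with an empty pool keep their
#'   row with \code{NA} statistics.
#' @export
rankSummaries <- function(d, metadata) {
  md <- metadata[match(rownames(d), metadata$sequence_id), , drop = FALSE]
  eqRank <- function(v) {
    lab <- !is.na(v)
    outer(lab, lab, `&`) & outer(v, v, `==`) & !is.na(outer(v, v, `==`))
  }
  sameSp <- eqRank(md$species)
  sameGe <- eqRank(md$genus)
  sameFa <- eqRank(md$family)
  pools <- list(
    within_species = list(exclusive = sameSp, inclusive = sameSp),
    within_genus = list(exclusive = sameGe & !sameSp, inclusive = sameGe),
    within_family = list(exclusive = sameFa & !sameGe, inclusive = sameFa))
  nGroups <- c(within_species = length(unique(stats::na.omit(md$species))),
               within_genus = length(unique(stats::na.omit(md$genus))),
               within_family = length(unique(stats::na.omit(md$family))))
  out <- list()
  for (lev in names(pools))
    for (mode in c("exclusive", "inclusive")) {
      s <- .summarisePool(.pool(d, pools[[lev]][[mode]]))
      out[[paste(lev, mode)]] <- cbind(
        data.frame(level = lev, pooling = mode,
                   n_groups = nGroups[[lev]], stringsAsFactors = FALSE), s)
    }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
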