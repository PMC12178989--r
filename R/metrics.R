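.checkLabelPair <- function(tl, al) {
  if (length(tl) != length(al))
    stop("label vectors must have equal length (", length(tl), " vs ",
         length(al), ")")
  if (length(tl) < 1L) stop("empty label vectors")
  if (anyNA(tl) || anyNA(al)) stop("labels must not contain NA")
}

#' Contingency table of two labelings
#'
#' @param tl,al equal-length label vectors (true and assigned).
#' @return integer matrix of counts, rows = true classes, columns =
#'   assigned labels.
#' @export
contingencyTable <- function(tl, al) {
  .checkLabelPair(tl, al)
  unclass(table(tl, al))
}

#' Hubert-Arabie adjusted Rand index
#'
#' Chance-corrected pairwise agreement between two partitions,
#' `(Index - E[Index]) / (Max - E[Index])` over the `choose(N, 2)` object
#' pairs. 1 for identical partitions, about 0 for random labellings,
#' negative for systematic disagreement. The index is symmetric and
#' invariant to relabelling in either argument; it is exactly 0 whenever
#' either labelling is trivial (all objects together, or all objects apart)
#' and the other is not. In the degenerate case where the chance-correction
#' denominator vanishes (both labellings trivial in the same way), the
#' convention is 1 when the two partitions are identical and 0 otherwise.
#'
#' @param tl,al equal-length label vectors (N >= 2).
#' @return a score in `[-1, 1]`.
#' @export
ariScore <- function(tl, al) {
  .checkLabelPair(tl, al)
  n <- length(tl)
  if (n < 2L) stop("adjusted Rand requires at least two objects")
  ct <- contingencyTable(tl, al)
  ch2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(ch2(ct))
  sumI <- sum(ch2(rowSums(ct)))
  sumJ <- sum(ch2(colSums(ct)))
  expected <- sumI * sumJ / ch2(n)
  maxIdx <- (sumI + sumJ) / 2
  denom <- maxIdx - expected
  if (abs(denom) < .Machine$double.eps * max(1, maxIdx)) {
    # identical partitions iff classes and clusters correspond one-to-one
    same <- all(rowSums(ct > 0) == 1L) && all(colSums(ct > 0) == 1L)
    return(if (same) 1 else 0)
  }
  (sumIJ - expected) / denom
}

#' Normalised mutual information
#'
#' Mutual information of the joint label distribution, normalised by the
#' arithmetic mean of the two label entropies (natural log; the
#' normaliser cancels the base). 0 for independent labellings — in
#' particular whenever one labelling is constant, since zero entropy forces
#' zero mutual information — and 1 for identical partitions. When both
#' labellings are constant (both entropies zero) the partitions are
#' identical and the score is 1 by convention.
#'
#' @param tl,al equal-length label vectors.
#' @return a score in `[0, 1]`.
#' @export
nmiScore <- function(tl, al) {
  .checkLabelPair(tl, al)
  ct <- contingencyTable(tl, al)
  n <- sum(ct)
  pij <- ct / n
  pi <- rowSums(pij)
  pj <- colSums(pij)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hI <- ent(pi); hJ <- ent(pj)
  if (hI == 0 && hJ == 0) return(1)
  if (hI == 0 || hJ == 0) return(0)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi, pj)[nz]))
  max(0, min(1, mi / ((hI + hJ) / 2)))
}

#' Counting accuracy (many-to-one majority mapping)
#'
#' Each assigned cluster is mapped to its most frequent true class (several
#' clusters may map to one class); the score is the fraction of objects
#' whose mapped class equals their true class. The all-singletons labelling
#' therefore scores exactly 1: every singleton cluster maps to its own
#' object's class.
#'
#' @param tl,al equal-length label vectors.
#' @return a score in `(0, 1]`.
#' @export
countingAccuracy <- function(tl, al) {
  ct <- contingencyTable(tl, al)
  sum(apply(ct, 2L, max)) / sum(ct)
}

#' Hungarian algorithm accuracy (optimal one-to-one mapping)
#'
#' Clusters are assigned to true classes one-to-one so as to maximize the
#' total matched count (Hungarian method on the contingency table, padded
#' with zero rows/columns when the cluster and class counts differ;
#' unmatched clusters contribute nothing). The score is the matched count
#' divided by N. With C true classes, an all-singletons labelling scores
#' exactly `C / N`.
#'
#' @param tl,al equal-length label vectors.
#' @return a score in `[0, 1]`.
#' @export
hungarianAccuracy <- function(tl, al) {
  ct <- contingencyTable(tl, al)
  n <- max(dim(ct))
  P <- matrix(0, n, n)
  P[seq_len(nrow(ct)), seq_len(ncol(ct))] <- ct
  sol <- clue::solve_LSAP(P, maximum = TRUE)
  sum(P[cbind(seq_len(n), as.integer(sol))]) / sum(ct)
}

#' Score an assigned labelling against the truth with all four metrics
#'
#' @param tl,al equal-length label vectors (true and assigned).
#' @return one-row `data.frame` with columns `nmi`, `ari`, `acc`, `hacc`.
#' @export
metricReport <- function(tl, al) {
  data.frame(nmi = nmiScore(tl, al), ari = ariScore(tl, al),
             acc = countingAccuracy(tl, al), hacc = hungarianAccuracy(tl, al))
}

#' Label sanity battery
#'
#' Scores four synthetic labellings against a ground truth, probing whether
#' a metric can be fooled by degenerate output:
#' \describe{
#'   \item{RL}{Random Labels — N uniform random integers in `1..nClasses`.}
#'   \item{SL}{Same Labels — one constant label for all objects.}
#'   \item{DL}{Different Labels — a random permutation of `1..N` (every
#'     object its own cluster).}
#'   \item{RA}{Random Assigned — N uniform random integers in `1..nTracks`,
#'     emulating random assignment of objects to tracks.}
#' }
#' A trustworthy metric scores all four near zero. Counting accuracy gives
#' DL a perfect 1 and normalised mutual information scores DL well above
#' random, which is why the adjusted Rand index is the metric of choice for
#' comparing labellings whose cluster counts differ wildly.
#'
#' @param tl true label vector (length N >= nClasses).
#' @param nClasses number of classes for RL.
#' @param nTracks number of tracks for RA (at most N).
#' @param seed integer seed making the battery reproducible.
#' @return `data.frame` with rows RL, SL, DL, RA and columns
#'   `nmi, ari, acc, hacc`.
#' @export
sanityBattery <- function(tl, nClasses, nTracks, seed = 1L) {
  n <- length(tl)
  if (nClasses < 1L || n < nClasses) stop("need N >= nClasses >= 1")
  if (nTracks < 1L || nTracks > n) stop("need 1 <= nTracks <= N")
  set.seed(seed)
  labs <- list(RL = sample.int(nClasses, n, replace = TRUE),
               SL = rep(1L, n),
               DL = sample.int(n, n, replace = FALSE),
               RA = sample.int(nTracks, n, replace = TRUE))
  out <- do.call(rbind, lapply(labs, function(al) metricReport(tl, al)))
  rownames(out) <- names(labs)
  out
}

#' Incremental Friedman grouping of ranked methods
#'
#' Given per-dataset ranks of methods ordered best-first, tests the best
#' two methods for distinguishability with the Friedman rank test
#' (classical chi-square approximation, as in [stats::friedman.test()]),
#' then adds one method at a time, recomputing the p-value on the growing
#' sub-matrix, and stops at the first p-value below `alpha`. The returned
#' top group is the largest prefix of methods whose Friedman p-values all
#' stay at or above `alpha` — the methods statistically indistinguishable
#' from the best. Ranks are re-ranked within each dataset row for every
#' sub-matrix, as the Friedman test requires.
#'
#' @param ranks numeric matrix, rows = datasets, columns = methods ordered
#'   best (smallest mean rank) first.
#' @param alpha significance cut-off (default 0.05).
#' @return list with `topGroup` (prefix size; 1 when even the best two
#'   methods differ) and `pValues` (named vector, one per prefix size
#'   2..k, `NA` after the first rejection).
#' @export
incrementalFriedman <- function(ranks, alpha = 0.05) {
  ranks <- as.matrix(ranks)
  k <- ncol(ranks)
  if (k < 2L) stop("at least two methods required")
  if (nrow(ranks) < 2L) stop("at least two datasets required")
  if (is.null(colnames(ranks))) colnames(ranks) <- sprintf("m%d", seq_len(k))
  pvals <- rep(NA_real_, k - 1L)
  names(pvals) <- sprintf("top%d", 2:k)
  top <- k
  for (m in 2:k) {
    p <- stats::friedman.test(ranks[, seq_len(m), drop = FALSE])$p.value
    # a fully tied sub-matrix makes the statistic 0/0: perfectly
    # indistinguishable methods, so the evidence against H0 is nil
    if (is.nan(p)) p <- 1
    pvals[[m - 1L]] <- p
    if (is.na(p) || p < alpha) { top <- m - 1L; break }
  }
  list(topGroup = top, pValues = pvals)
}
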