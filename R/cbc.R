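#' Cannot-link constraints between tracks from frame co-occurrence
#'
#' Two animals visible in the same frame cannot be the same identity, so
#' two tracks with detections in a common frame must never be merged. The
#' pair (p, q) is returned exactly when some frame contains a detection
#' labelled p and a detection labelled q.
#'
#' @param dataset a [TrackedDataset-class].
#' @param labels integer track labels aligned with the detections.
#' @return an unordered, irreflexive constraint set as a two-column integer
#'   matrix (columns `p`, `q`, with `p < q`), zero rows when no tracks
#'   co-occur.
#' @export
trackCLConstraints <- function(dataset, labels) {
  stopifnot(is(dataset, "TrackedDataset"))
  if (length(labels) != nDetections(dataset))
    stop("labels must align with detections")
  pairs <- lapply(detectionsByFrame(dataset), function(idx) {
    u <- sort(unique(labels[idx]))
    if (length(u) < 2L) return(NULL)
    t(utils::combn(u, 2L))
  })
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs))
    pairs <- matrix(integer(0), 0L, 2L)
  pairs <- unique(pairs)
  colnames(pairs) <- c("p", "q")
  pairs
}

# Dispatch helper: classifier may be a ReIDClassifier or a plain function.
.resubstitute <- function(classifier, X, labels) {
  pred <- if (is.function(classifier)) classifier(X, labels)
          else fitPredict(classifier, X, labels)
  if (length(pred) != length(labels))
    stop("classifier returned ", length(pred), " labels for ",
         length(labels), " observations")
  pred
}

#' @describeIn fitPredict nearest-centroid resubstitution: each observation
#'   is assigned the label of the class whose centroid is nearest in
#'   Euclidean distance (ties to the lowest label).
#' @export
setMethod("fitPredict", "NearestCentroidClassifier", function(classifier, X, labels) {
  X <- as.matrix(X)
  cls <- sort(unique(labels))
  cent <- t(vapply(cls, function(k) colMeans(X[labels == k, , drop = FALSE]),
                   numeric(ncol(X))))
  # squared distances via expansion; drop the ||x||^2 term (constant per row)
  d2 <- -2 * X %*% t(cent)
  d2 <- sweep(d2, 2L, rowSums(cent^2), "+")
  cls[max.col(-d2, ties.method = "first")]
})

#' @describeIn fitPredict delegate to the wrapped function.
#' @export
setMethod("fitPredict", "FunctionClassifier", function(classifier, X, labels)
  classifier@fun(X, labels))

#' Masked, row-scaled resubstitution confusion matrix
#'
#' The merge-decision matrix of classifier-based clustering. A classifier
#' is trained on the feature data with the current track labels and used to
#' relabel the same data (resubstitution); the resulting confusion counts
#' are masked — diagonal zeroed (correct classifications carry no merge
#' information) and both entries of every cannot-link pair zeroed (a
#' constrained pair must never merge) — and each row is scaled to sum to 1.
#' Entry (i, j) is then the proportion of current track i labelled as
#' current track j; a large proportion suggests the two tracks are the same
#' identity. Rows whose masked counts are all zero are left all-zero.
#'
#' @param X numeric feature matrix, one row per detection.
#' @param labels integer track labels, one per row of `X` (at least two
#'   distinct values).
#' @param cl cannot-link constraint matrix from [trackCLConstraints()].
#' @param classifier a [ReIDClassifier-class] or a `function(X, labels)`.
#' @return a [MergeMatrix-class] whose row/column names are the sorted
#'   distinct labels (as characters).
#' @export
mergeMatrix <- function(X, labels, cl = matrix(integer(0), 0L, 2L),
                        classifier = nearestCentroidClassifier()) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("every detection must be featurized")
  if (nrow(X) != length(labels)) stop("labels must align with rows of X")
  cls <- sort(unique(labels))
  if (length(cls) < 2L) stop("at least two distinct labels required")
  pred <- .resubstitute(classifier, X, labels)
  f <- function(v) factor(v, levels = cls)
  M <- unclass(table(f(labels), f(pred)))
  M <- matrix(as.numeric(M), nrow(M), dimnames = list(cls, cls))
  diag(M) <- 0
  if (nrow(cl) > 0L) {
    p <- match(cl[, 1L], cls); q <- match(cl[, 2L], cls)
    ok <- !is.na(p) & !is.na(q)
    M[cbind(p[ok], q[ok])] <- 0
    M[cbind(q[ok], p[ok])] <- 0
  }
  rs <- rowSums(M)
  rs[rs == 0] <- 1                      # all-zero rows stay all-zero
  new("MergeMatrix", values = M / rs)
}

#' @describeIn MergeMatrix-class the matrix values (dimnames are the track
#'   labels).
#' @param x a `MergeMatrix`.
#' @export
mergeValues <- function(x) x@values

setMethod("show", "MergeMatrix", function(object) {
  v <- object@values
  cat("MergeMatrix over", nrow(v), "tracks;",
      sum(v > 0), "candidate merges, max entry",
      format(if (length(v)) max(v) else 0, digits = 4), "\n")
})

#' Classifier-based clustering of tracks into identities
#'
#' Merges the tracker's tracks down to `K` identities. Starting from the
#' input track labels, each iteration (i) trains the classifier on the
#' features under the current labels and computes the masked, row-scaled
#' resubstitution confusion matrix ([mergeMatrix()]), with cannot-link
#' constraints recomputed from the current labels' frame co-occurrence;
#' (ii) finds the largest matrix entry; (iii) if that value is zero
#' (nothing available to merge) or the number of current tracks equals `K`,
#' stops and returns the current labels; otherwise merges the row track
#' into the column track by relabelling all the row track's detections to
#' the column label, and repeats. Ties for the largest entry are broken by
#' the lowest row label, then the lowest column label.
#'
#' Since every step only ever relabels one whole track to another track's
#' label, the output is a coarsening of the input tracks (no track is ever
#' split), and the loop performs at most `n_tracks - K` merges — fewer when
#' cannot-link constraints block the remaining merges, in which case more
#' than `K` labels are returned.
#'
#' @param dataset a featurized [TrackedDataset-class].
#' @param trackLabels integer track labels aligned with the detections
#'   (default: the dataset's own `tracks()`).
#' @param K desired number of identities. If `K` is not smaller than the
#'   number of input tracks, the track labels are returned unchanged.
#' @param classifier a [ReIDClassifier-class] or a `function(X, labels)`;
#'   default nearest-centroid.
#' @return integer vector of identity labels, one per detection (a subset
#'   of the input track labels).
#' @export
cbcCluster <- function(dataset, trackLabels = tracks(dataset), K,
                       classifier = nearestCentroidClassifier()) {
  stopifnot(is(dataset, "TrackedDataset"), K >= 1)
  if (!hasFeatures(dataset))
    stop("every detection must be featurized before clustering")
  if (length(trackLabels) != nDetections(dataset) || anyNA(trackLabels))
    stop("trackLabels must be a complete labelling aligned with detections")
  X <- featureMatrix(dataset)
  labels <- as.integer(trackLabels)
  if (K >= length(unique(labels))) return(labels)
  while (length(unique(labels)) > K) {
    cl <- trackCLConstraints(dataset, labels)
    M <- mergeValues(mergeMatrix(X, labels, cl, classifier))
    top <- max(M)
    if (top <= 0) break                  # nothing available to merge
    hits <- which(M == top, arr.ind = TRUE)
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    from <- as.integer(rownames(M)[hits[1L, 1L]])
    to <- as.integer(colnames(M)[hits[1L, 2L]])
    labels[labels == from] <- to
  }
  labels
}
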