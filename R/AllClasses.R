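#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.FEATURE_DIM <- 54L

.requiredDetectionCols <- c("frame", "x", "y", "w", "h", "track", "identity")

#' TrackedDataset: detections of a tracked video
#'
#' A `TrackedDataset` holds the output of a multiple-object tracker for one
#' video clip: one column per detection (a bounding box in one frame), with
#' the appearance feature vector of each detection as the single assay
#' (`"features"`, 54 rows by default, `NA` until extracted), and the
#' per-detection annotations as `colData`:
#' \describe{
#'   \item{frame}{0-based frame index of the detection.}
#'   \item{x, y, w, h}{axis-aligned bounding box, 0-based pixel coordinates
#'     of the top-left corner plus width and height; half-open extent
#'     `[x, x + w) x [y, y + h)`.}
#'   \item{track}{track label assigned by the tracker (`NA` when untracked).}
#'   \item{identity}{ground-truth identity (`NA` when unknown).}
#' }
#' The number of frames in the clip is kept in `metadata()$nFrames`.
#' Detections are stored frame-major (non-decreasing frame index).
#'
#' @aliases TrackedDataset
#' @exportClass TrackedDataset
setClass("TrackedDataset", contains = "SummarizedExperiment")

setValidity("TrackedDataset", function(object) {
  cd <- SummarizedExperiment::colData(object)
  missing <- setdiff(.requiredDetectionCols, colnames(cd))
  if (length(missing) > 0L)
    return(paste("missing detection columns:", paste(missing, collapse = ", ")))
  if (ncol(object) < 1L)
    return("a TrackedDataset must contain at least one detection")
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  fr <- cd$frame
  if (any(is.na(fr)) || any(fr < 0L))
    return("frame indices must be non-negative and non-missing")
  if (is.unsorted(fr))
    return("detections must be ordered frame-major")
  if (any(!is.finite(cd$x)) || any(!is.finite(cd$y)))
    return("box coordinates must be finite")
  if (any(!is.finite(cd$w)) || any(cd$w <= 0) ||
      any(!is.finite(cd$h)) || any(cd$h <= 0))
    return("box width and height must be finite and positive")
  nf <- S4Vectors::metadata(object)$nFrames
  if (is.null(nf) || length(nf) != 1L || is.na(nf) || nf < max(fr) + 1L)
    return("metadata nFrames must cover all frame indices (>= max frame + 1)")
  TRUE
})

#' MergeMatrix: masked, row-scaled resubstitution confusion matrix
#'
#' Square matrix over the current track labels driving classifier-based
#' clustering. Entry (i, j) is the proportion of track i's members that the
#' resubstitution classifier relabelled as track j, after zeroing the
#' diagonal and all cannot-link pairs and scaling each row to sum to one
#' (rows whose masked counts are all zero stay all-zero).
#'
#' @aliases MergeMatrix
#' @exportClass MergeMatrix
setClass("MergeMatrix", representation(values = "matrix"))

setValidity("MergeMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("row and column names must be identical track labels")
  if (any(v < 0)) return("entries must be non-negative")
  if (nrow(v) > 0L && any(abs(diag(v)) > 1e-12)) return("diagonal must be zero")
  rs <- rowSums(v)
  if (any(abs(rs) > 1e-8 & abs(rs - 1) > 1e-8))
    return("each row must sum to 1 or be all-zero")
  TRUE
})

#' CentroidSet: per-track centroids in feature space
#'
#' One row per distinct track: the arithmetic mean of the feature vectors of
#' the track's member detections. Used by the centroid-clustering baselines;
#' `trackOf` records each detection's track so that centroid-level cluster
#' labels can be propagated back to detections.
#'
#' @aliases CentroidSet
#' @exportClass CentroidSet
setClass("CentroidSet",
         representation(centroids = "matrix", trackLabels = "integer",
                        trackOf = "integer"))

setValidity("CentroidSet", function(object) {
  if (nrow(object@centroids) != length(object@trackLabels))
    return("one centroid row per track label required")
  if (anyDuplicated(object@trackLabels) > 0L)
    return("track labels must be unique")
  if (!all(object@trackOf %in% object@trackLabels))
    return("trackOf contains labels with no centroid")
  TRUE
})

#' Classifier specifications for classifier-based clustering
#'
#' `ReIDClassifier` is the virtual parent of pluggable classifier
#' specifications; concrete classes implement [fitPredict()].
#' `NearestCentroidClassifier` (constructor [nearestCentroidClassifier()])
#' classifies each observation to the class with the nearest (Euclidean)
#' centroid; it tolerates single-member classes, which are common among
#' fragmented tracks. `FunctionClassifier` wraps a plain
#' `function(X, labels)` returning predicted labels.
#'
#' @aliases ReIDClassifier NearestCentroidClassifier FunctionClassifier
#' @exportClass ReIDClassifier
#' @exportClass NearestCentroidClassifier
#' @exportClass FunctionClassifier
setClass("ReIDClassifier", representation("VIRTUAL"))

setClass("NearestCentroidClassifier", contains = "ReIDClassifier")

setClass("FunctionClassifier", contains = "ReIDClassifier",
         representation(fun = "function"))

#' @describeIn ReIDClassifier-class nearest-centroid classifier (the default
#'   model used by [cbcCluster()]).
#' @export
nearestCentroidClassifier <- function() new("NearestCentroidClassifier")

#' @describeIn ReIDClassifier-class wrap a `function(X, labels)` as a
#'   classifier specification.
#' @param fun a `function(X, labels)` returning one predicted label per row.
#' @export
functionClassifier <- function(fun) {
  stopifnot(is.function(fun))
  new("FunctionClassifier", fun = fun)
}
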