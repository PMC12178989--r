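#' Construct a TrackedDataset
#'
#' @param frame integer vector of 0-based frame indices, one per detection.
#' @param x,y,w,h numeric vectors of bounding boxes (top-left corner, width,
#'   height, in pixels; half-open extent).
#' @param track optional integer vector of track labels (`NA` = untracked).
#' @param identity optional integer vector of ground-truth identities.
#' @param features optional numeric matrix of appearance features, either
#'   `N x d` (detections as rows) or `d x N`; defaults to an all-`NA`
#'   54-row assay.
#' @param nFrames number of frames in the clip; defaults to `max(frame) + 1`.
#' @param featureDim feature dimension used when `features` is `NULL`.
#' @return a [TrackedDataset-class] with detections ordered frame-major.
#' @examples
#' td <- TrackedDataset(frame = c(0, 0, 1), x = c(0, 40, 2), y = c(0, 0, 0),
#'                      w = rep(10, 3), h = rep(10, 3), identity = c(1, 2, 1))
#' nDetections(td)
#' @export
TrackedDataset <- function(frame, x, y, w, h, track = NA_integer_,
                           identity = NA_integer_, features = NULL,
                           nFrames = NULL, featureDim = 54L) {
  n <- length(frame)
  df <- S4Vectors::DataFrame(
    frame = as.integer(frame),
    x = as.numeric(x), y = as.numeric(y),
    w = as.numeric(w), h = as.numeric(h),
    track = rep_len(as.integer(track), n),
    identity = rep_len(as.integer(identity), n))
  if (is.null(features)) {
    features <- matrix(NA_real_, nrow = featureDim, ncol = n,
                       dimnames = list(featureNames(featureDim), NULL))
  } else {
    features <- as.matrix(features)
    if (ncol(features) == n && nrow(features) != n) {
      # already d x N
    } else if (nrow(features) == n) {
      features <- t(features)
    } else {
      stop("features must have one row or one column per detection")
    }
    if (is.null(rownames(features)) && nrow(features) == .FEATURE_DIM)
      rownames(features) <- featureNames()
  }
  ord <- order(df$frame)        # stable: preserves input order within a frame
  df <- df[ord, , drop = FALSE]
  features <- features[, ord, drop = FALSE]
  if (is.null(nFrames)) nFrames <- max(df$frame) + 1L
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = features), colData = df,
    metadata = list(nFrames = as.integer(nFrames)))
  colnames(se) <- sprintf("det%d", seq_len(n))
  new("TrackedDataset", se)
}

#' Standard 54-feature names of the RGB grid descriptor
#'
#' @param d feature dimension; names are descriptive only for the default 54.
#' @return character vector of length `d`
#'   (`cell{1..9}_{R,G,B}_{mean,std}` for `d = 54`).
#' @export
featureNames <- function(d = 54L) {
  if (d == .FEATURE_DIM) {
    grid <- expand.grid(stat = c("mean", "std"), channel = c("R", "G", "B"),
                        cell = 1:9)
    sprintf("cell%d_%s_%s", grid$cell, grid$channel, grid$stat)
  } else {
    sprintf("f%d", seq_len(d))
  }
}

#' @describeIn TrackedDataset-class 0-based frame index of each detection.
#' @param x a `TrackedDataset`.
#' @export
setMethod("frameIndex", "TrackedDataset", function(x, ...)
  SummarizedExperiment::colData(x)$frame)

#' @describeIn TrackedDataset-class bounding boxes as a `data.frame` with
#'   columns `x`, `y`, `w`, `h`.
#' @export
setMethod("boxes", "TrackedDataset", function(x, ...)
  as.data.frame(SummarizedExperiment::colData(x)[, c("x", "y", "w", "h")]))

#' @describeIn TrackedDataset-class track label of each detection.
#' @export
setMethod("tracks", "TrackedDataset", function(x, ...)
  SummarizedExperiment::colData(x)$track)

#' @describeIn TrackedDataset-class replace the track labels.
#' @param value integer vector of track labels, one per detection.
#' @export
setReplaceMethod("tracks", "TrackedDataset", function(x, value) {
  if (length(value) != ncol(x))
    stop("track labels must align with detections (length ", ncol(x), ")")
  SummarizedExperiment::colData(x)$track <- as.integer(value)
  x
})

#' @describeIn TrackedDataset-class ground-truth identity of each detection.
#' @export
setMethod("identities", "TrackedDataset", function(x, ...)
  SummarizedExperiment::colData(x)$identity)

#' @describeIn TrackedDataset-class appearance features as an `N x d` matrix
#'   (detections as rows), the orientation clustering functions expect.
#' @export
setMethod("featureMatrix", "TrackedDataset", function(x, ...)
  t(SummarizedExperiment::assay(x, "features")))

#' @describeIn TrackedDataset-class `TRUE` when every detection carries a
#'   complete feature vector.
#' @export
setMethod("hasFeatures", "TrackedDataset", function(x)
  !anyNA(SummarizedExperiment::assay(x, "features")))

#' @describeIn TrackedDataset-class number of frames in the clip.
#' @export
setMethod("nFrames", "TrackedDataset", function(x)
  S4Vectors::metadata(x)$nFrames)

#' @describeIn TrackedDataset-class number of detections.
#' @export
setMethod("nDetections", "TrackedDataset", function(x) ncol(x))

setMethod("show", "TrackedDataset", function(object) {
  ids <- identities(object)
  trk <- tracks(object)
  cat("TrackedDataset with", ncol(object), "detections over",
      nFrames(object), "frames\n")
  cat("  tracks:    ",
      if (all(is.na(trk))) "none assigned"
      else length(unique(trk[!is.na(trk)])), "\n")
  cat("  identities:",
      if (all(is.na(ids))) "unknown"
      else length(unique(ids[!is.na(ids)])), "\n")
  cat("  features:  ", nrow(object), "dims,",
      if (hasFeatures(object)) "extracted" else "not extracted", "\n")
})

#' Per-frame and per-track detection lookup
#'
#' @param x a [TrackedDataset-class].
#' @return `detectionsByFrame`: a list, one element per occupied frame (named
#'   by frame index), of detection indices in that frame.
#'   `detectionsByTrack`: the same keyed by track label, each track's
#'   detections in frame order.
#' @export
detectionsByFrame <- function(x) {
  split(seq_len(ncol(x)), frameIndex(x))
}

#' @rdname detectionsByFrame
#' @export
detectionsByTrack <- function(x) {
  trk <- tracks(x)
  keep <- !is.na(trk)
  split(seq_len(ncol(x))[keep], trk[keep])
}
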