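#' Intersection over union of two axis-aligned boxes
#'
#' Computed on the continuous box areas (not rasterized pixels): for boxes
#' with half-open extents the IoU is `|A intersect B| / |A union B|`. The
#' measure is symmetric, 1 exactly for identical boxes, 0 exactly when the
#' interiors are disjoint.
#'
#' @param a,b boxes as numeric vectors `c(x, y, w, h)` with positive width
#'   and height.
#' @return IoU ratio in `[0, 1]`.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 0, 2, 2))  # 1/3
#' @export
iou <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 4L || length(b) != 4L ||
      any(!is.finite(c(a, b))) || a[3L] <= 0 || a[4L] <= 0 ||
      b[3L] <= 0 || b[4L] <= 0)
    stop("boxes must be c(x, y, w, h) with positive width and height")
  iw <- min(a[1L] + a[3L], b[1L] + b[3L]) - max(a[1L], b[1L])
  ih <- min(a[2L] + a[4L], b[2L] + b[4L]) - max(a[2L], b[2L])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (a[3L] * a[4L] + b[3L] * b[4L] - inter)
}

# All-pairs IoU between two box matrices (rows = boxes, cols = x,y,w,h).
.iouMatrix <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B)
  M <- matrix(0, nA, nB)
  for (i in seq_len(nA))
    for (j in seq_len(nB))
      M[i, j] <- iou(A[i, ], B[j, ])
  M
}

#' Associate detections of two adjacent frames
#'
#' Solves the one-to-one assignment between the boxes of the previous and
#' the current frame that maximizes total IoU, with pairs below the IoU
#' threshold inadmissible (never matched). The optimum is found with the
#' Hungarian method on the IoU weight matrix; matched pairs whose IoU falls
#' below the threshold are discarded afterwards, which leaves an optimal
#' admissible matching (a pair contributing weight below the threshold
#' never raises the total over leaving both boxes unmatched).
#'
#' @param prevBoxes,curBoxes numeric matrices of boxes, one row per
#'   detection, columns `x, y, w, h` (either may have zero rows).
#' @param threshold minimum IoU for an admissible match, in `(0, 1]`.
#' @return a list with `matches` (two-column integer matrix of
#'   previous-row / current-row index pairs), `unmatchedPrev` and
#'   `unmatchedCurrent` (integer vectors).
#' @export
associateFrames <- function(prevBoxes, curBoxes, threshold = 0.7) {
  prevBoxes <- .asBoxMatrix(prevBoxes)
  curBoxes <- .asBoxMatrix(curBoxes)
  stopifnot(threshold > 0, threshold <= 1)
  nP <- nrow(prevBoxes); nC <- nrow(curBoxes)
  empty <- list(matches = matrix(integer(0), 0L, 2L,
                                 dimnames = list(NULL, c("prev", "cur"))),
                unmatchedPrev = seq_len(nP), unmatchedCurrent = seq_len(nC))
  if (nP == 0L || nC == 0L) return(empty)
  W <- .iouMatrix(prevBoxes, curBoxes)
  W[W < threshold] <- 0
  if (all(W == 0)) return(empty)
  # pad to square so every row can be assigned; zero-weight pads are dropped
  n <- max(nP, nC)
  Wp <- matrix(0, n, n)
  Wp[seq_len(nP), seq_len(nC)] <- W
  sol <- clue::solve_LSAP(Wp, maximum = TRUE)
  prevIdx <- seq_len(nP)
  curIdx <- as.integer(sol)[seq_len(nP)]
  keep <- curIdx <= nC & W[cbind(prevIdx, pmin(curIdx, nC))] >= threshold
  matches <- cbind(prev = prevIdx[keep], cur = curIdx[keep])
  list(matches = matches,
       unmatchedPrev = setdiff(seq_len(nP), matches[, 1L]),
       unmatchedCurrent = setdiff(seq_len(nC), matches[, 2L]))
}

.asBoxMatrix <- function(b) {
  if (is.data.frame(b)) b <- as.matrix(b[, c("x", "y", "w", "h")])
  if (is.null(dim(b))) b <- matrix(b, ncol = 4L, byrow = TRUE)
  storage.mode(b) <- "double"
  b
}

#' Build tracks by IoU-gated association across consecutive frames
#'
#' The track generator walks the frames in order; for every pair of
#' adjacent frames it computes all pairwise IoUs and solves the Hungarian
#' assignment (see [associateFrames()]). A current-frame detection matched
#' to a previous-frame detection continues that detection's track; an
#' unmatched detection starts a new track. Association is strictly between
#' adjacent frames: a detection unmatched for even one frame (including
#' across a gap of empty frames) starts a new track. Track labels are
#' integers numbered in order of track creation, starting at 1.
#'
#' @param dataset a [TrackedDataset-class] (features not required).
#' @param threshold minimum IoU for a match; the default 0.7 demands a 70%
#'   overlap between the boxes.
#' @return integer vector of track labels, one per detection, aligned with
#'   the dataset. Assign it with `tracks(dataset) <- buildTracks(dataset)`.
#' @export
buildTracks <- function(dataset, threshold = 0.7) {
  stopifnot(is(dataset, "TrackedDataset"))
  byFrame <- detectionsByFrame(dataset)
  b <- .asBoxMatrix(boxes(dataset))
  labels <- integer(ncol(dataset))
  nextLabel <- 1L
  prevFrame <- -2L
  prevIdx <- integer(0)
  for (fr in names(byFrame)) {
    j <- as.integer(fr)
    curIdx <- byFrame[[fr]]
    if (j == prevFrame + 1L && length(prevIdx) > 0L) {
      assoc <- associateFrames(b[prevIdx, , drop = FALSE],
                               b[curIdx, , drop = FALSE], threshold)
      m <- assoc$matches
      if (nrow(m) > 0L)
        labels[curIdx[m[, 2L]]] <- labels[prevIdx[m[, 1L]]]
      newOnes <- assoc$unmatchedCurrent
    } else {
      newOnes <- seq_along(curIdx)
    }
    for (i in newOnes) {
      labels[curIdx[i]] <- nextLabel
      nextLabel <- nextLabel + 1L
    }
    prevFrame <- j
    prevIdx <- curIdx
  }
  labels
}
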