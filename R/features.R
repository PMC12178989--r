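#' Read a video frame image as an RGB intensity array
#'
#' @param path path to a PNG/JPEG/TIFF image.
#' @return numeric array `height x width x 3` of 8-bit intensities (0-255).
#' @export
readFrame <- function(path) {
  if (!file.exists(path)) stop("frame image not found: ", path)
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 2L)
    stop("non-RGB image (single channel): ", path)
  if (d[[3L]] > 3L) img <- img[, , 1:3]        # drop alpha
  if (dim(img)[[3L]] != 3L) stop("non-RGB image: ", path)
  aperm(EBImage::imageData(img), c(2L, 1L, 3L)) * 255
}

# Pixel column/row range covered by a continuous half-open interval
# [a, a + len), clamped to [0, limit).
.pixelRange <- function(a, len, limit) {
  lo <- max(0L, as.integer(floor(a)))
  hi <- min(as.integer(limit), as.integer(ceiling(a + len)))
  c(lo, hi)
}

#' Extract the 54-dimensional RGB grid descriptor of a bounding box
#'
#' The box (clamped to the image bounds) is split into a 3-by-3 grid of
#' cells; from each cell the mean and the standard deviation of each colour
#' plane (R/G/B) are taken, giving 9 cells x 3 colours x 2 statistics = 54
#' features, on the raw 0-255 intensity scale. Cell boundaries fall at
#' `floor(i * w / 3)` (and likewise for height), so cell sizes may differ
#' by one pixel; the cells partition the box exactly. The standard
#' deviation is the population form (divide by n): the statistic describes
#' the cell, it does not estimate anything.
#'
#' @param image numeric array `height x width x 3`, intensities 0-255 (as
#'   from [readFrame()]).
#' @param box bounding box as a numeric vector `c(x, y, w, h)` (0-based
#'   top-left corner, width, height in pixels).
#' @return numeric vector of length 54, ordered cell-major (grid row-major),
#'   within each cell channel-major (R, G, B), within each channel
#'   (mean, std); named as [featureNames()].
#' @examples
#' img <- array(c(200, 10, 30)[rep(1:3, each = 100)], dim = c(10, 10, 3))
#' f <- extractFeatures(img, c(2, 2, 6, 6))
#' all(f[grepl("R_mean", names(f))] == 200)
#' @export
extractFeatures <- function(image, box) {
  d <- dim(image)
  if (length(d) != 3L || d[[3L]] != 3L)
    stop("image must be a height x width x 3 RGB array")
  box <- as.numeric(box)
  if (length(box) != 4L || any(!is.finite(box)) || box[[3L]] <= 0 || box[[4L]] <= 0)
    stop("box must be c(x, y, w, h) with positive width and height")
  cr <- .pixelRange(box[[1L]], box[[3L]], d[[2L]])   # columns
  rr <- .pixelRange(box[[2L]], box[[4L]], d[[1L]])   # rows
  cw <- cr[[2L]] - cr[[1L]]
  ch <- rr[[2L]] - rr[[1L]]
  if (cw < 3L || ch < 3L)
    stop("box clamped to image bounds must span at least 3x3 pixels ",
         "(got ", max(cw, 0L), "x", max(ch, 0L), ")")
  colEdges <- cr[[1L]] + floor((0:3) * cw / 3)
  rowEdges <- rr[[1L]] + floor((0:3) * ch / 3)
  out <- numeric(.FEATURE_DIM)
  k <- 0L
  for (gr in 1:3) {
    rows <- (rowEdges[[gr]] + 1L):rowEdges[[gr + 1L]]
    for (gc in 1:3) {
      cols <- (colEdges[[gc]] + 1L):colEdges[[gc + 1L]]
      for (chan in 1:3) {
        v <- image[rows, cols, chan]
        m <- mean(v)
        out[[k + 1L]] <- m
        out[[k + 2L]] <- sqrt(mean((v - m)^2))
        k <- k + 2L
      }
    }
  }
  names(out) <- featureNames()
  out
}

#' Extract appearance features for every detection of a dataset
#'
#' @param dataset a [TrackedDataset-class].
#' @param frames either a directory of frame images or a list of in-memory
#'   RGB arrays indexed by frame (element `j + 1` holds frame `j`); defaults
#'   to the `framesDir` recorded by [readAnnotations()].
#' @param framePattern `sprintf` pattern mapping a frame number to its file
#'   name within the directory.
#' @param frameBase frame number of the first video frame in the file names
#'   (default 1, matching MOTChallenge image naming).
#' @return the dataset with the `features` assay filled in. The operation is
#'   deterministic, hence idempotent.
#' @export
featurizeDataset <- function(dataset, frames = NULL,
                             framePattern = "frame_%06d.png",
                             frameBase = 1L) {
  stopifnot(is(dataset, "TrackedDataset"))
  if (is.null(frames)) frames <- S4Vectors::metadata(dataset)$framesDir
  if (is.null(frames)) stop("no frame source: supply 'frames'")
  byFrame <- detectionsByFrame(dataset)
  b <- boxes(dataset)
  feat <- matrix(NA_real_, nrow = .FEATURE_DIM, ncol = ncol(dataset),
                 dimnames = list(featureNames(), colnames(dataset)))
  for (fr in names(byFrame)) {
    j <- as.integer(fr)
    if (is.list(frames)) {
      if (j + 1L > length(frames) || is.null(frames[[j + 1L]]))
        stop("missing frame image for frame ", j)
      img <- frames[[j + 1L]]
    } else {
      path <- file.path(frames, sprintf(framePattern, j + frameBase))
      if (!file.exists(path))
        stop("missing frame image for frame ", j, ": ", path)
      img <- readFrame(path)
    }
    for (i in byFrame[[fr]])
      feat[, i] <- extractFeatures(img, c(b$x[i], b$y[i], b$w[i], b$h[i]))
  }
  SummarizedExperiment::assay(dataset, "features") <- feat
  dataset
}

#' Column-standardize a feature matrix
#'
#' z-scores each feature dimension; dimensions with zero spread are mapped
#' to 0. Distance-based clustering baselines use this scaling by default
#' (an epsilon on the order of 0.5-4 only makes sense in a standardized
#' space); classifier-based clustering works on the raw 0-255 scale.
#'
#' @param X numeric matrix, detections as rows.
#' @return matrix of the same shape.
#' @export
scaleFeatures <- function(X) {
  X <- as.matrix(X)
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- Inf
  sweep(sweep(X, 2L, mu, "-"), 2L, sd, "/")
}
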