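#' Represent each track by its feature-space centroid
#'
#' Collapses a featurized dataset to one point per track: the arithmetic
#' mean of the feature vectors of the track's member detections. The
#' centroid-clustering comparators operate on this reduced dataset.
#'
#' @param dataset a featurized [TrackedDataset-class].
#' @param labels track labels aligned with the detections (default the
#'   dataset's own).
#' @return a [CentroidSet-class].
#' @export
trackCentroids <- function(dataset, labels = tracks(dataset)) {
  stopifnot(is(dataset, "TrackedDataset"))
  if (!hasFeatures(dataset)) stop("dataset must be featurized")
  if (length(labels) != nDetections(dataset) || anyNA(labels))
    stop("labels must be a complete labelling aligned with detections")
  X <- featureMatrix(dataset)
  labels <- as.integer(labels)
  cls <- sort(unique(labels))
  cent <- t(vapply(cls, function(k) colMeans(X[labels == k, , drop = FALSE]),
                   numeric(ncol(X))))
  rownames(cent) <- cls
  new("CentroidSet", centroids = cent, trackLabels = cls, trackOf = labels)
}

#' @describeIn CentroidSet-class the centroid matrix (tracks as rows).
#' @param x a `CentroidSet`.
#' @export
centroids <- function(x) x@centroids

setMethod("show", "CentroidSet", function(object) {
  cat("CentroidSet:", nrow(object@centroids), "track centroids in",
      ncol(object@centroids), "feature dimensions\n")
})

#' Propagate centroid-level cluster labels back to detections
#'
#' After clustering track centroids, every detection inherits the cluster
#' label of its track, so the result is always a coarsening of the tracks.
#'
#' @param centroidLabels cluster labels, one per track — either named by
#'   track label, or aligned with `sort(unique(trackLabels))` (the row
#'   order of [trackCentroids()]).
#' @param trackLabels track labels, one per detection.
#' @return integer vector of detection labels.
#' @export
propagateCentroidLabels <- function(centroidLabels, trackLabels) {
  universe <- if (!is.null(names(centroidLabels))) {
    as.integer(names(centroidLabels))
  } else {
    sort(unique(as.integer(trackLabels)))
  }
  if (length(centroidLabels) != length(universe))
    stop("one centroid label per track required")
  idx <- match(as.integer(trackLabels), universe)
  if (anyNA(idx))
    stop("track label(s) with no centroid label: ",
         paste(unique(trackLabels[is.na(idx)]), collapse = ", "))
  as.integer(centroidLabels)[idx]
}

# --- DBSCAN ---------------------------------------------------------------
# Classical density-based clustering (region queries over a Euclidean
# distance matrix; core point = at least minPts neighbours within eps,
# itself included). Noise points get label 0.
.dbscanLabels <- function(D, eps, minPts) {
  n <- nrow(D)
  nbrs <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nbrs, length, 1L) >= minPts
  labels <- integer(n)                  # 0 = unvisited/noise
  cluster <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cluster <- cluster + 1L
    queue <- i
    labels[i] <- cluster
    while (length(queue) > 0L) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (q in nbrs[[p]]) {
        if (labels[q] == 0L) {
          labels[q] <- cluster
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

#' Off-the-shelf clustering comparators
#'
#' The comparator battery applied to raw detection features or to track
#' centroids: k-means, seven agglomerative linkages, a Gaussian mixture
#' (shared diagonal covariance, at most 1000 EM iterations), DBSCAN with
#' the parameter sweep described below, and spectral clustering. DBSCAN
#' does not take a cluster count, so it is run over the grid
#' `eps in {0.5, 1.0, ..., 4.0}` times `minPts in {1, ..., 8}` and the run
#' whose cluster count is closest to `K` is returned (ties broken by the
#' smaller eps, then the smaller minPts); noise points are returned as
#' singleton clusters so that every row is labelled. That epsilon grid
#' presumes standardized features (see [scaleFeatures()]). `"finch"` is
#' recognised but unsupported (no implementation available).
#'
#' @param method one of `"kmeans"`, `"average"`, `"centroid"`,
#'   `"complete"`, `"median"`, `"single"`, `"ward"`, `"weighted"`,
#'   `"gmm"`, `"dbscan"`, `"spectral"`, `"finch"`.
#' @param data numeric matrix, observations as rows.
#' @param K desired number of clusters (passed to every K-aware method).
#' @param seed integer seed for the stochastic methods.
#' @return integer cluster labels, one per row of `data`.
#' @export
clusterBaseline <- function(method, data, K, seed = 1L) {
  data <- as.matrix(data)
  n <- nrow(data)
  stopifnot(K >= 1, n >= 1)
  methods <- c("kmeans", "average", "centroid", "complete", "median",
               "single", "ward", "weighted", "gmm", "dbscan", "spectral",
               "finch")
  if (!method %in% methods)
    stop("unknown clustering method: '", method, "'")
  if (method == "finch")
    stop("method 'finch' is not supported: no implementation is available")
  K <- min(as.integer(K), n)
  if (K == n && method != "dbscan") return(seq_len(n))
  set.seed(seed)
  labels <- switch(method,
    kmeans = stats::kmeans(data, centers = K, nstart = 10L,
                           iter.max = 100L)$cluster,
    gmm = {
      bic <- mclust::mclustBIC(data, G = K, modelNames = "EEI",
                               control = mclust::emControl(itmax = 1000L),
                               verbose = FALSE)
      fit <- mclust::summaryMclustBIC(bic, data, G = K, modelNames = "EEI")
      if (is.null(fit$classification))
        stop("Gaussian mixture fit failed for K = ", K)
      fit$classification
    },
    dbscan = {
      D <- as.matrix(stats::dist(data))
      best <- NULL
      for (eps in seq(0.5, 4.0, by = 0.5)) {
        for (minPts in 1:8) {
          lab <- .dbscanLabels(D, eps, minPts)
          nc <- length(unique(lab[lab > 0L]))
          if (is.null(best) || abs(nc - K) < abs(best$nc - K))
            best <- list(lab = lab, nc = nc, eps = eps, minPts = minPts)
        }
      }
      lab <- best$lab
      noise <- which(lab == 0L)
      lab[noise] <- max(lab) + seq_along(noise)   # noise = singletons
      lab
    },
    spectral = {
      if (K == 1L) rep(1L, n)
      else as.integer(kernlab::specc(data, centers = K))
    },
    {                                    # hierarchical linkages
      hm <- c(average = "average", centroid = "centroid",
              complete = "complete", median = "median", single = "single",
              ward = "ward.D2", weighted = "mcquitty")[[method]]
      d <- stats::dist(data)
      if (hm %in% c("centroid", "median")) d <- d^2
      stats::cutree(stats::hclust(d, method = hm), k = K)
    })
  as.integer(labels)
}
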