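#' Cluster the detections of a tracked, featurized dataset
#'
#' Dispatcher over the re-identification approaches: `"tracks-only"` uses
#' the track labels as the identities (no post-clustering); `"cbc"` runs
#' classifier-based clustering of the tracks ([cbcCluster()]);
#' `"raw-<alg>"` clusters the detection features directly with a baseline
#' algorithm, ignoring tracks; `"centroid-<alg>"` clusters the track
#' centroids and propagates the cluster labels back to the detections
#' (`<alg>` is any method of [clusterBaseline()]). The distance-based
#' baselines work on standardized features ([scaleFeatures()]); CBC works
#' on the raw intensity scale.
#'
#' @param dataset a featurized [TrackedDataset-class] with track labels
#'   (tracks are not needed for `raw-*` methods).
#' @param method approach name, see above.
#' @param K desired number of identities.
#' @param seed seed for stochastic baselines.
#' @param classifier classifier for `"cbc"` (default nearest-centroid).
#' @return integer identity labels, one per detection.
#' @export
clusterDetections <- function(dataset, method, K, seed = 1L,
                              classifier = nearestCentroidClassifier()) {
  stopifnot(is(dataset, "TrackedDataset"))
  needTracks <- method %in% c("tracks-only", "cbc") || startsWith(method, "centroid-")
  if (needTracks && anyNA(tracks(dataset)))
    stop("method '", method, "' needs track labels; run buildTracks() first")
  if (method == "tracks-only") return(tracks(dataset))
  if (method == "cbc")
    return(cbcCluster(dataset, tracks(dataset), K, classifier))
  if (startsWith(method, "raw-")) {
    alg <- sub("^raw-", "", method)
    X <- scaleFeatures(featureMatrix(dataset))
    return(clusterBaseline(alg, X, K, seed))
  }
  if (startsWith(method, "centroid-")) {
    alg <- sub("^centroid-", "", method)
    cs <- trackCentroids(dataset)
    clab <- clusterBaseline(alg, scaleFeatures(centroids(cs)), K, seed)
    names(clab) <- cs@trackLabels
    return(propagateCentroidLabels(clab, tracks(dataset)))
  }
  stop("unknown re-identification method: '", method, "'")
}

#' Run the full re-identification pipeline
#'
#' Wires the stages end to end: read annotations (or a precomputed feature
#' table), extract appearance features, build tracks by IoU association,
#' cluster the tracks into `K` identities, write the label map, and — when
#' ground truth is present — score it. All stage outputs are plain files,
#' and a manifest of every parameter is written next to them so a run can
#' be reproduced exactly.
#'
#' @param annotations path to a MOTChallenge-style ground-truth CSV
#'   (ignored when `featureTable` is given).
#' @param framesDir directory of frame images (required unless
#'   `featureTable` is given).
#' @param featureTable optional precomputed feature table
#'   ([writeFeatureTable()] layout) that bypasses image input.
#' @param outDir output directory for `labels.csv`, `metrics.csv` and
#'   `manifest.txt`.
#' @param method re-identification approach, see [clusterDetections()].
#' @param K desired number of identities.
#' @param iouThreshold IoU gate of the track builder.
#' @param seed integer seed.
#' @param frameBase frame numbering base of the input files.
#' @param framePattern frame image file-name pattern.
#' @return (invisibly) a list with `labels`, `dataset`, `metrics` (`NULL`
#'   without ground truth) and `outDir`.
#' @export
runPipeline <- function(annotations = NULL, framesDir = NULL,
                        featureTable = NULL, outDir, method = "cbc", K,
                        iouThreshold = 0.7, seed = 1L, frameBase = 1L,
                        framePattern = "frame_%06d.png") {
  if (is.null(featureTable) && is.null(annotations))
    stop("either 'annotations' or 'featureTable' is required")
  dataset <- if (!is.null(featureTable)) {
    readFeatureTable(featureTable)
  } else {
    td <- readAnnotations(annotations, framesDir, frameBase = frameBase)
    if (method != "tracks-only" || !is.null(framesDir))
      td <- featurizeDataset(td, framesDir, framePattern, frameBase)
    td
  }
  if (anyNA(tracks(dataset)))
    tracks(dataset) <- buildTracks(dataset, iouThreshold)
  labels <- clusterDetections(dataset, method, K, seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeLabels(dataset, labels, file.path(outDir, "labels.csv"), frameBase)
  metrics <- NULL
  gt <- identities(dataset)
  if (!anyNA(gt)) {
    metrics <- metricReport(gt, labels)
    utils::write.csv(metrics, file.path(outDir, "metrics.csv"),
                     row.names = FALSE)
  }
  manifest <- c(annotations = annotations %||% "", framesDir = framesDir %||% "",
                featureTable = featureTable %||% "", method = method, K = K,
                iouThreshold = iouThreshold, seed = seed,
                frameBase = frameBase, framePattern = framePattern)
  writeLines(paste0(names(manifest), "=", unlist(manifest)),
             file.path(outDir, "manifest.txt"))
  invisible(list(labels = labels, dataset = dataset, metrics = metrics,
                 outDir = outDir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a key=value run configuration file
#'
#' One `key=value` pair per line; blank lines and `#` comments are
#' ignored. Keys outside `allowed` are rejected.
#'
#' @param path file path.
#' @param allowed character vector of permitted keys (default: the
#'   [runPipeline()] arguments).
#' @return named character vector.
#' @export
readRunConfig <- function(path,
                          allowed = setdiff(names(formals(runPipeline)), "")) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  eq <- regexpr("=", lines, fixed = TRUE)
  if (any(eq < 0)) stop("malformed config line: ", lines[eq < 0][[1L]])
  keys <- trimws(substr(lines, 1L, eq - 1L))
  vals <- trimws(substr(lines, eq + 1L, nchar(lines)))
  unknown <- setdiff(keys, allowed)
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  stats::setNames(vals, keys)
}
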