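#' Read a MOTChallenge-style annotation file
#'
#' Parses a CSV of per-frame bounding boxes with columns
#' `frame, id, x, y, w, h` (any further columns are ignored; an optional
#' header row is detected and skipped). Rows are ordered frame-major, with
#' file order preserved within a frame. Frame numbers in the file are
#' converted to the package's 0-based convention by subtracting `frameBase`
#' (MOTChallenge files are 1-based, the default).
#'
#' @param path path to the annotation CSV.
#' @param framesDir optional directory of frame images, recorded for later
#'   feature extraction.
#' @param idColumn whether the file's id column holds ground-truth
#'   identities (the default) or tracker-assigned track labels.
#' @param frameBase frame number of the first video frame in the file
#'   (default 1).
#' @return a [TrackedDataset-class]; `nFrames` is `max(frame) + 1` after
#'   rebasing.
#' @export
readAnnotations <- function(path, framesDir = NULL,
                            idColumn = c("identity", "track"),
                            frameBase = 1L) {
  idColumn <- match.arg(idColumn)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("annotation file is empty: ", path)
  first <- strsplit(lines[[1L]], ",", fixed = TRUE)[[1L]]
  skip <- is.na(suppressWarnings(as.numeric(trimws(first[[1L]]))))
  if (skip) lines <- lines[-1L]
  if (length(lines) == 0L) stop("annotation file has no data rows: ", path)
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 6L)
  if (length(bad) > 0L)
    stop("malformed annotation row (fewer than 6 fields) at line ",
         bad[[1L]] + skip)
  num <- function(k) {
    v <- suppressWarnings(as.numeric(vapply(parts, function(p) trimws(p[[k]]), "")))
    if (anyNA(v))
      stop("malformed annotation row (non-numeric field ", k, ") at line ",
           which(is.na(v))[[1L]] + skip)
    v
  }
  frame <- num(1L) - frameBase
  id <- num(2L)
  w <- num(5L); h <- num(6L)
  if (any(frame < 0))
    stop("frame number below frameBase (", frameBase, ") at line ",
         which(frame < 0)[[1L]] + skip)
  if (any(w <= 0 | h <= 0))
    stop("non-positive box width/height at line ",
         which(w <= 0 | h <= 0)[[1L]] + skip)
  td <- TrackedDataset(
    frame = frame, x = num(3L), y = num(4L), w = w, h = h,
    track = if (idColumn == "track") as.integer(id) else NA_integer_,
    identity = if (idColumn == "identity") as.integer(id) else NA_integer_)
  if (!is.null(framesDir))
    S4Vectors::metadata(td)$framesDir <- framesDir
  td
}

#' Write a per-detection label map
#'
#' Emits the labelled map of the video: one CSV row per detection with
#' columns `frame, assigned_label, x, y, w, h, ground_truth` (ground truth
#' left empty when unknown), in dataset order. Frame indices are written
#' rebased to `frameBase`; box coordinates with two decimal places. The
#' file re-reads with [readAnnotations()] (the assigned label is the id
#' column).
#'
#' @param dataset a [TrackedDataset-class].
#' @param labels integer label vector aligned with the detections.
#' @param path output file path.
#' @param frameBase frame number to give the first video frame (default 1).
#' @return `path`, invisibly.
#' @export
writeLabels <- function(dataset, labels, path, frameBase = 1L) {
  stopifnot(is(dataset, "TrackedDataset"))
  if (length(labels) != nDetections(dataset))
    stop("labels must align with detections: expected ",
         nDetections(dataset), ", got ", length(labels))
  b <- boxes(dataset)
  gt <- identities(dataset)
  rows <- sprintf("%d,%d,%.2f,%.2f,%.2f,%.2f,%s",
                  frameIndex(dataset) + as.integer(frameBase),
                  as.integer(labels), b$x, b$y, b$w, b$h,
                  ifelse(is.na(gt), "", as.character(gt)))
  writeLines(c("frame,assigned_label,x,y,w,h,ground_truth", rows), path)
  invisible(path)
}

#' Read or write a per-detection feature table
#'
#' Delimited numeric text with a header row: columns `frame`, `track`,
#' `identity` (empty when unknown) followed by one named column per feature
#' dimension.
#'
#' @param dataset a featurized [TrackedDataset-class].
#' @param path file path.
#' @return `writeFeatureTable`: `path` invisibly. `readFeatureTable`: a
#'   [TrackedDataset-class] with unit boxes (the table carries no geometry).
#' @export
writeFeatureTable <- function(dataset, path) {
  stopifnot(is(dataset, "TrackedDataset"))
  fm <- featureMatrix(dataset)
  df <- data.frame(frame = frameIndex(dataset), track = tracks(dataset),
                   identity = identities(dataset), fm, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("frame", "track", "identity")
  if (!all(need %in% colnames(df)))
    stop("feature table must have columns frame, track, identity")
  fm <- as.matrix(df[, setdiff(colnames(df), need), drop = FALSE])
  if (ncol(fm) < 1L || !is.numeric(fm)) stop("no numeric feature columns found")
  TrackedDataset(frame = df$frame, x = 0, y = 0, w = 1, h = 1,
                 track = df$track, identity = df$identity, features = fm)
}
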