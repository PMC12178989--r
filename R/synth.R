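#' Derive an independent RNG seed for a named stream
#'
#' All randomness in the simulators flows from one master seed through
#' named streams (motion, appearance, schedule), so one component can be
#' varied while the others stay fixed.
#'
#' @param seed master integer seed.
#' @param stream stream name.
#' @return integer seed in `[0, 2^31)`.
#' @export
streamSeed <- function(seed, stream) {
  u <- utf8ToInt(stream)
  h <- sum(u * seq_along(u))
  as.integer((abs(as.numeric(seed)) * 104729 + h * 7919) %% 2147483647)
}

#' Configuration of a rendered synthetic scene
#'
#' Describes a clip of same-species "animals" — noisy coloured ellipses —
#' moving in an arena. `pen` bounds the animals inside the frame
#' (reflective walls, like a camera covering a whole pen); `open` lets them
#' wander out of view and re-enter later with probability `reentryProb` per
#' frame, which fragments their tracks exactly as exit/re-entry does in
#' hand-held footage. Occlusion arises from overlap and is rendered with
#' the painter's algorithm under a per-frame z-order; the ground-truth box
#' is always the full (unoccluded) ellipse extent clipped to the frame,
#' matching the annotation practice of drawing the whole animal, and is
#' dropped when fewer than 3x3 pixels remain in frame. With
#' `allowOverlap = FALSE` each animal keeps to its own horizontal lane, so
#' boxes never overlap.
#'
#' @param nIdentities number of animals (>= 1).
#' @param nFrames number of frames.
#' @param frameSize frame `c(width, height)` in pixels.
#' @param animalSize ellipse extent `c(w, h)` in pixels.
#' @param appearanceSeparation mean pairwise distance between the
#'   identities' base RGB colours (8-bit intensity units).
#' @param textureNoise per-pixel intensity noise s.d. within an animal.
#' @param motionStep random-walk step s.d. in pixels/frame.
#' @param arena `"pen"` (reflective bounds) or `"open"` (exit/re-entry).
#' @param reentryProb per-frame re-entry probability while out of view.
#' @param allowOverlap whether animals may overlap (occlusion).
#' @param seed master seed; the scene is a deterministic function of the
#'   configuration.
#' @return a `SceneConfig` object for [simulateScene()].
#' @aliases SceneConfig-class
#' @exportClass SceneConfig
#' @export
SceneConfig <- function(nIdentities = 4L, nFrames = 60L,
                        frameSize = c(96L, 96L), animalSize = c(24, 16),
                        appearanceSeparation = 120, textureNoise = 8,
                        motionStep = 1, arena = c("pen", "open"),
                        reentryProb = 0.1, allowOverlap = TRUE, seed = 1L) {
  arena <- match.arg(arena)
  new("SceneConfig", nIdentities = as.integer(nIdentities),
      nFrames = as.integer(nFrames), frameSize = as.integer(frameSize),
      animalSize = as.numeric(animalSize),
      appearanceSeparation = as.numeric(appearanceSeparation),
      textureNoise = as.numeric(textureNoise),
      motionStep = as.numeric(motionStep), arena = arena,
      reentryProb = as.numeric(reentryProb),
      allowOverlap = isTRUE(allowOverlap), seed = as.integer(seed))
}

setClass("SceneConfig",
         representation(nIdentities = "integer", nFrames = "integer",
                        frameSize = "integer", animalSize = "numeric",
                        appearanceSeparation = "numeric",
                        textureNoise = "numeric", motionStep = "numeric",
                        arena = "character", reentryProb = "numeric",
                        allowOverlap = "logical", seed = "integer"))

setValidity("SceneConfig", function(object) {
  if (object@nIdentities < 1L) return("nIdentities must be >= 1")
  if (object@nFrames < 1L) return("nFrames must be >= 1")
  if (object@reentryProb < 0 || object@reentryProb > 1)
    return("reentryProb must be a probability")
  if (!object@arena %in% c("pen", "open")) return("unknown arena type")
  lanes <- if (object@allowOverlap) 1L else object@nIdentities
  if (any(object@animalSize + 2 > object@frameSize / c(1L, lanes)))
    return("frame too small for the configured animals")
  TRUE
})

# Base colours with a given mean pairwise separation, centred mid-range.
.identityColors <- function(nId, separation) {
  if (nId == 1L)
    return(matrix(pmin(pmax(128 + stats::rnorm(3, 0, 40), 0), 255), 1L))
  dev <- matrix(stats::rnorm(nId * 3), nId, 3L)
  d0 <- mean(stats::dist(dev))
  cols <- 128 + dev * separation / d0
  pmin(pmax(cols, 0), 255)
}

#' Render a synthetic multi-animal scene
#'
#' @param config a [SceneConfig()].
#' @return a list with `frames` (list of `height x width x 3` arrays,
#'   intensities 0-255), `dataset` (a [TrackedDataset-class] carrying the
#'   ground-truth identities; tracks unset), and `config`. Identical
#'   configurations give bit-identical output.
#' @export
simulateScene <- function(config) {
  stopifnot(is(config, "SceneConfig"))
  validObject(config)
  W <- config@frameSize[[1L]]; H <- config@frameSize[[2L]]
  nId <- config@nIdentities; nF <- config@nFrames
  aw <- config@animalSize[[1L]]; ah <- config@animalSize[[2L]]

  # lane bounds per identity (whole frame when overlap is allowed)
  laneH <- if (config@allowOverlap) H else H / nId
  laneTop <- if (config@allowOverlap) rep(0, nId) else (seq_len(nId) - 1L) * laneH

  # --- motion stream: centre trajectories + visibility -------------------
  set.seed(streamSeed(config@seed, "motion"))
  cx <- matrix(NA_real_, nF, nId); cy <- matrix(NA_real_, nF, nId)
  out <- matrix(FALSE, nF, nId)
  px <- stats::runif(nId, aw / 2, W - aw / 2)
  py <- laneTop + stats::runif(nId, ah / 2, laneH - ah / 2)
  gone <- rep(FALSE, nId)
  reflect <- function(v, lo, hi) {
    span <- hi - lo
    v <- (v - lo) %% (2 * span)
    lo + ifelse(v > span, 2 * span - v, v)
  }
  for (f in seq_len(nF)) {
    for (i in seq_len(nId)) {
      if (gone[i]) {
        if (stats::runif(1) < config@reentryProb) {
          gone[i] <- FALSE                       # re-enter at a random edge
          side <- sample(c(-1, 1), 1L)
          px[i] <- if (side < 0) 1 - aw / 2 else W - 1 + aw / 2
          py[i] <- stats::runif(1, ah / 2, H - ah / 2)
        }
      } else {
        px[i] <- px[i] + stats::rnorm(1, 0, config@motionStep)
        py[i] <- py[i] + stats::rnorm(1, 0, config@motionStep)
        if (config@arena == "pen" || !config@allowOverlap) {
          px[i] <- reflect(px[i], aw / 2, W - aw / 2)
          py[i] <- reflect(py[i], laneTop[i] + ah / 2,
                           laneTop[i] + laneH - ah / 2)
        } else if (px[i] + aw / 2 <= 0 || px[i] - aw / 2 >= W ||
                   py[i] + ah / 2 <= 0 || py[i] - ah / 2 >= H) {
          gone[i] <- TRUE                        # fully left the view
        }
      }
      cx[f, i] <- px[i]; cy[f, i] <- py[i]; out[f, i] <- gone[i]
    }
  }

  # --- schedule stream: per-frame z-order --------------------------------
  set.seed(streamSeed(config@seed, "schedule"))
  zorder <- lapply(seq_len(nF), function(f) sample.int(nId))

  # --- appearance stream: colours, then per-pixel rendering noise --------
  set.seed(streamSeed(config@seed, "appearance"))
  cols <- .identityColors(nId, config@appearanceSeparation)
  bg <- c(105, 95, 80)                           # dull ground
  frames <- vector("list", nF)
  det <- list(frame = integer(0), x = numeric(0), y = numeric(0),
              w = numeric(0), h = numeric(0), identity = integer(0))
  for (f in seq_len(nF)) {
    img <- array(rep(bg, each = H * W), dim = c(H, W, 3L))
    for (i in zorder[[f]]) {
      if (out[f, i]) next
      x0 <- cx[f, i] - aw / 2; y0 <- cy[f, i] - ah / 2
      rows <- max(1L, floor(y0) + 1L):min(H, ceiling(y0 + ah))
      colsIdx <- max(1L, floor(x0) + 1L):min(W, ceiling(x0 + aw))
      if (length(rows) < 1L || length(colsIdx) < 1L) next
      rc <- expand.grid(r = rows, c = colsIdx)
      inside <- ((rc$c - 0.5 - cx[f, i]) / (aw / 2))^2 +
                ((rc$r - 0.5 - cy[f, i]) / (ah / 2))^2 <= 1
      rc <- rc[inside, , drop = FALSE]
      if (nrow(rc) == 0L) next
      for (chan in 1:3) {
        noise <- stats::rnorm(nrow(rc), 0, config@textureNoise)
        img[cbind(rc$r, rc$c, chan)] <-
          pmin(pmax(cols[i, chan] + noise, 0), 255)
      }
    }
    for (i in seq_len(nId)) {                    # ground-truth boxes
      if (out[f, i]) next
      x0 <- cx[f, i] - aw / 2; y0 <- cy[f, i] - ah / 2
      cxl <- max(x0, 0); cyl <- max(y0, 0)
      cwl <- min(x0 + aw, W) - cxl; chl <- min(y0 + ah, H) - cyl
      if (cwl < 3 || chl < 3) next               # too little visible
      det$frame <- c(det$frame, f - 1L)
      det$x <- c(det$x, x0); det$y <- c(det$y, y0)
      det$w <- c(det$w, aw); det$h <- c(det$h, ah)
      det$identity <- c(det$identity, i)
    }
    frames[[f]] <- img
  }
  if (length(det$frame) == 0L)
    stop("scene produced no visible detections; enlarge the frame or ",
         "raise reentryProb")
  dataset <- TrackedDataset(frame = det$frame, x = det$x, y = det$y,
                            w = det$w, h = det$h, identity = det$identity,
                            nFrames = nF)
  list(frames = frames, dataset = dataset, config = config)
}

#' Write a simulated scene to disk
#'
#' Writes the frames as zero-padded PNG files and the ground truth as a
#' MOTChallenge-style CSV (`gt.csv`: frame, identity, x, y, w, h; 1-based
#' frames), the exact layout [readAnnotations()] and [featurizeDataset()]
#' consume.
#'
#' @param scene result of [simulateScene()].
#' @param dir output directory (created if needed).
#' @param framePattern `sprintf` pattern for frame file names.
#' @return `dir`, invisibly.
#' @export
writeScene <- function(scene, dir, framePattern = "frame_%06d.png") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in seq_along(scene$frames)) {
    img <- aperm(scene$frames[[f]] / 255, c(2L, 1L, 3L))
    EBImage::writeImage(EBImage::Image(img, colormode = "Color"),
                        file.path(dir, sprintf(framePattern, f)))
  }
  d <- scene$dataset
  b <- boxes(d)
  writeLines(sprintf("%d,%d,%.2f,%.2f,%.2f,%.2f", frameIndex(d) + 1L,
                     identities(d), b$x, b$y, b$w, b$h),
             file.path(dir, "gt.csv"))
  invisible(dir)
}

#' Configuration of a feature-space track simulation
#'
#' Emulates tracker output directly in feature space, skipping rendering:
#' each identity is a spherical Gaussian cloud in feature space; each
#' identity's presence span is split into several tracks (fragmentation),
#' and identities co-occur in frames according to the schedule, which
#' creates cannot-link constraints between their tracks.
#'
#' @param nIdentities number of identities.
#' @param nFrames number of frames; each scheduled identity contributes one
#'   detection per frame.
#' @param featureDim feature dimensionality (54, as the RGB grid descriptor).
#' @param separation mean pairwise Euclidean distance between identity
#'   means in feature space.
#' @param spread within-identity spread: the typical Euclidean distance of
#'   a detection from its identity mean (the cloud is isotropic Gaussian
#'   with per-dimension s.d. `spread / sqrt(featureDim)`, so the root
#'   mean squared point-to-mean distance equals `spread`).
#' @param driftScale typical Euclidean length of a constant per-track
#'   offset added to the identity mean (concept drift between fragments of
#'   one identity), on the same distance scale as `spread`.
#' @param fragmentation expected number of tracks per identity (>= 1); the
#'   count is `1 + Poisson(fragmentation - 1)`, capped so every fragment
#'   can reach `minTrackLen`.
#' @param minTrackLen minimum length of a track fragment, in frames.
#'   Fragments model exit/re-entry (or occlusion) episodes: an animal that
#'   is tracked at all is tracked for at least a short dwell time, so the
#'   span is split uniformly over all compositions with parts at least
#'   this long.
#' @param nSimultaneous number of identities present in any one frame (the
#'   co-occurrence schedule); defaults to all of them, and may not exceed
#'   `nIdentities`.
#' @param identityMeans optional `nIdentities x featureDim` matrix of means
#'   overriding the generated ones.
#' @param seed master seed.
#'
#' @details `separation` and `spread` are both Euclidean distances in the
#' full feature space, so `separation / spread` is the
#' appearance-separability ratio quoted in the package's recovery
#' experiments (the defaults give 75 / 15 = 5). Scaling both by the
#' dimension keeps the ratio meaningful regardless of `featureDim`.
#' @return a `FeatureTrackConfig` for [simulateFeatureTracks()].
#' @aliases FeatureTrackConfig-class
#' @exportClass FeatureTrackConfig
#' @export
FeatureTrackConfig <- function(nIdentities = 8L, nFrames = 120L,
                               featureDim = 54L, separation = 75,
                               spread = 15, driftScale = 0,
                               fragmentation = 3, minTrackLen = 5L,
                               nSimultaneous = nIdentities,
                               identityMeans = NULL, seed = 1L) {
  new("FeatureTrackConfig", nIdentities = as.integer(nIdentities),
      nFrames = as.integer(nFrames), featureDim = as.integer(featureDim),
      separation = as.numeric(separation), spread = as.numeric(spread),
      driftScale = as.numeric(driftScale),
      fragmentation = as.numeric(fragmentation),
      minTrackLen = as.integer(minTrackLen),
      nSimultaneous = as.integer(nSimultaneous),
      identityMeans = if (is.null(identityMeans)) matrix(numeric(0), 0L, 0L)
                      else as.matrix(identityMeans),
      seed = as.integer(seed))
}

setClass("FeatureTrackConfig",
         representation(nIdentities = "integer", nFrames = "integer",
                        featureDim = "integer", separation = "numeric",
                        spread = "numeric", driftScale = "numeric",
                        fragmentation = "numeric", minTrackLen = "integer",
                        nSimultaneous = "integer",
                        identityMeans = "matrix", seed = "integer"))

setValidity("FeatureTrackConfig", function(object) {
  if (object@nIdentities < 1L) return("nIdentities must be >= 1")
  if (object@fragmentation < 1) return("fragmentation rate must be >= 1")
  if (object@minTrackLen < 1L) return("minTrackLen must be >= 1")
  if (object@nSimultaneous < 1L || object@nSimultaneous > object@nIdentities)
    return("impossible schedule: nSimultaneous must be in [1, nIdentities]")
  if (nrow(object@identityMeans) > 0L &&
      (nrow(object@identityMeans) != object@nIdentities ||
       ncol(object@identityMeans) != object@featureDim))
    return("identityMeans must be nIdentities x featureDim")
  TRUE
})

#' Simulate fragmented tracks directly in feature space
#'
#' @param config a [FeatureTrackConfig()].
#' @return a featurized [TrackedDataset-class] with track labels and
#'   ground-truth identities. Ground truth never places two detections of
#'   one identity in the same frame; track labels are numbered by order of
#'   first appearance. Boxes are placeholder unit-lane boxes (the
#'   simulation carries no geometry).
#' @export
simulateFeatureTracks <- function(config) {
  stopifnot(is(config, "FeatureTrackConfig"))
  validObject(config)
  nId <- config@nIdentities; nF <- config@nFrames; d <- config@featureDim

  # schedule stream: which identities appear in which frames
  set.seed(streamSeed(config@seed, "schedule"))
  present <- matrix(FALSE, nF, nId)
  for (f in seq_len(nF)) {
    who <- if (config@nSimultaneous == nId) seq_len(nId)
           else sample.int(nId, config@nSimultaneous)
    present[f, who] <- TRUE
  }
  if (!all(colSums(present) > 0L))
    present[1L, ] <- TRUE                        # every identity appears

  # appearance stream: identity means, track drifts, detection features
  set.seed(streamSeed(config@seed, "appearance"))
  means <- if (nrow(config@identityMeans) > 0L) config@identityMeans else {
    dev <- matrix(stats::rnorm(nId * d), nId, d)
    if (nId > 1L) 128 + dev * config@separation / mean(stats::dist(dev))
    else 128 + dev
  }

  frame <- integer(0); identity <- integer(0); track <- integer(0)
  feats <- NULL
  nextTrack <- 0L
  minLen <- config@minTrackLen
  for (i in seq_len(nId)) {
    fr <- which(present[, i]) - 1L
    span <- length(fr)
    nFrag <- min(1L + stats::rpois(1L, config@fragmentation - 1),
                 max(1L, span %/% minLen))
    frag <- if (nFrag == 1L) rep(1L, span) else {
      # uniform composition of the span into nFrag parts of >= minLen frames
      free <- span - nFrag * minLen
      cuts <- sort(sample.int(free + nFrag - 1L, nFrag - 1L))
      rep(seq_len(nFrag), diff(c(0L, cuts, free + nFrag)) - 1L + minLen)
    }
    # spread/driftScale are full-space distances; per-dimension sd scales
    # by 1/sqrt(d) so the RMS point-to-mean distance equals the scale
    offsets <- matrix(stats::rnorm(nFrag * d, 0, config@driftScale / sqrt(d)),
                      nFrag, d)
    x <- means[rep(i, length(fr)), , drop = FALSE] +
      offsets[frag, , drop = FALSE] +
      matrix(stats::rnorm(length(fr) * d, 0, config@spread / sqrt(d)),
             length(fr), d)
    frame <- c(frame, fr)
    identity <- c(identity, rep(i, length(fr)))
    track <- c(track, nextTrack + frag)
    feats <- rbind(feats, x)
    nextTrack <- nextTrack + nFrag
  }
  td <- TrackedDataset(frame = frame, x = (identity - 1) * 12, y = 0,
                       w = 10, h = 10, track = track, identity = identity,
                       features = feats, nFrames = nF, featureDim = d)
  # renumber tracks by order of first appearance
  trk <- tracks(td)
  first <- match(unique(trk), trk)
  relabel <- integer(max(trk))
  relabel[trk[sort(first)]] <- seq_along(first)
  tracks(td) <- relabel[trk]
  td
}
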