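# two tracks that never share a frame, one pair that co-occurs in frame 7
cooccurDataset <- function() {
  TrackedDataset(frame = c(1, 7, 7, 9), x = c(0, 0, 30, 30), y = 0,
                 w = 10, h = 10, track = c(1L, 1L, 2L, 2L))
}

test_that("cannot-link pairs are exactly the frame co-occurrences", {
  td <- cooccurDataset()
  cl <- trackCLConstraints(td, tracks(td))
  expect_equal(unname(cl), matrix(c(1L, 2L), 1))
  # temporally disjoint tracks: no constraints
  td2 <- TrackedDataset(frame = c(0, 1, 2, 3), x = 0, y = 0, w = 5, h = 5,
                        track = c(1L, 1L, 2L, 2L))
  expect_equal(nrow(trackCLConstraints(td2, tracks(td2))), 0L)
})

test_that("three staggered tracks constrain only the overlapping pair", {
  # track spans: {1-5}, {4-8}, {9-12}
  frame <- c(1:5, 4:8, 9:12)
  trk <- rep(1:3, c(5, 5, 4))
  td <- TrackedDataset(frame = frame, x = trk * 20, y = 0, w = 5, h = 5,
                       track = trk)
  cl <- trackCLConstraints(td, tracks(td))
  expect_equal(unname(cl), matrix(c(1L, 2L), 1))
  # exhaustive frame-scan oracle over all pairs
  oracle <- NULL
  for (p in 1:2) for (q in (p + 1):3) {
    if (length(intersect(frame[trk == p], frame[trk == q])) > 0)
      oracle <- rbind(oracle, c(p, q))
  }
  expect_equal(unname(cl), oracle)
})

test_that("merge matrix is masked, row-scaled, and matches a nearest-centroid oracle", {
  set.seed(14)
  means <- rbind(c(0, 0), c(10, 0), c(0, 10))
  trk <- rep(1:3, each = 15)
  td <- makeLabelledDataset(means, trk, frameOfDet = seq_along(trk) %% 20,
                            spread = 4, seed = 14)
  X <- featureMatrix(td)
  labels <- tracks(td)
  pred <- oracleNearestCentroid(X, labels)
  raw <- matrix(0, 3, 3, dimnames = list(1:3, 1:3))
  for (i in seq_along(labels)) raw[labels[i], pred[i]] <- raw[labels[i], pred[i]] + 1
  diag(raw) <- 0
  cl <- rbind(c(2L, 3L))
  raw[2, 3] <- 0; raw[3, 2] <- 0
  rs <- rowSums(raw); rs[rs == 0] <- 1
  M <- mergeValues(mergeMatrix(X, labels, cl))
  expect_equal(M, raw / rs, tolerance = 1e-12)
  expect_equal(unname(diag(M)), rep(0, 3))
  expect_equal(unname(c(M["2", "3"], M["3", "2"])), c(0, 0))
  expect_true(all(abs(rowSums(M)) < 1e-8 | abs(rowSums(M) - 1) < 1e-8))
})

test_that("merge matrix construction validates its input", {
  X <- matrix(rnorm(20), 10)
  expect_error(mergeMatrix(X, rep(1L, 10)), "two distinct")
  expect_error(mergeMatrix(X, rep(1:2, 4)), "align")
  X[1, 1] <- NA
  expect_error(mergeMatrix(X, rep(1:2, 5)), "featurized")
})

test_that("K at or above the track count returns the tracks unchanged", {
  td <- simulateFeatureTracks(FeatureTrackConfig(nIdentities = 3L,
                                                 nFrames = 12L,
                                                 fragmentation = 2,
                                                 seed = 2L))
  nT <- length(unique(tracks(td)))
  expect_identical(cbcCluster(td, K = nT), tracks(td))
  expect_identical(cbcCluster(td, K = nT + 5L), tracks(td))
})

test_that("same-appearance tracks merge; distinct track survives", {
  set.seed(8)
  # tracks 1 and 2 drawn from one distribution, track 3 far away; no CL
  means <- rbind(c(0, 0, 0), c(0, 0, 0), c(50, 50, 50))
  trk <- rep(1:3, each = 12)
  frame <- c(0:11, 12:23, seq(1, 23, 2))   # 1 and 2 disjoint in time
  td <- makeLabelledDataset(means, trk, frame, spread = 2, seed = 8)
  out <- cbcCluster(td, K = 2)
  expect_equal(length(unique(out)), 2L)
  truth <- c(1L, 1L, 2L)[tracks(td)]
  expect_equal(ariScore(truth, out), 1)
})

test_that("cannot-link blocking exits with more labels than K", {
  set.seed(15)
  # two co-occurring tracks with identical appearance, K = 1
  trk <- rep(1:2, 10)
  td <- makeLabelledDataset(rbind(c(0, 0), c(0, 0)), trk,
                            frameOfDet = rep(0:9, each = 2), spread = 1,
                            seed = 15)
  out <- cbcCluster(td, K = 1)
  expect_equal(sort(unique(out)), 1:2)     # merge blocked, 2 labels remain
})

test_that("the output coarsens the input tracks and respects frames", {
  for (seed in c(3L, 4L)) {
    td <- simulateFeatureTracks(FeatureTrackConfig(nIdentities = 4L,
                                                   nFrames = 30L,
                                                   fragmentation = 3,
                                                   seed = seed))
    trk <- tracks(td)
    K <- 4L
    out <- cbcCluster(td, K = K)
    # coarsening: all members of an input track share one output label
    for (t in unique(trk))
      expect_equal(length(unique(out[trk == t])), 1L)
    # clean input tracks => no output cluster holds two same-frame detections
    for (idx in detectionsByFrame(td))
      expect_false(any(duplicated(out[idx])))
    # at most nTracks - K merges
    expect_gte(length(unique(out)), K)
    # determinism
    expect_identical(out, cbcCluster(td, K = K))
  }
})

test_that("a plain function can serve as the classifier", {
  td <- simulateFeatureTracks(FeatureTrackConfig(nIdentities = 2L,
                                                 nFrames = 10L,
                                                 fragmentation = 2,
                                                 seed = 6L))
  out <- cbcCluster(td, K = 2L,
                    classifier = function(X, labels) oracleNearestCentroid(X, labels))
  expect_identical(out, cbcCluster(td, K = 2L))
  out2 <- cbcCluster(td, K = 2L,
                     classifier = functionClassifier(function(X, labels) labels))
  # an identity classifier never confuses tracks: nothing merges
  expect_identical(out2, tracks(td))
})
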