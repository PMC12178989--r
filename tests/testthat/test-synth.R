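test_that("a single penned animal yields one identity and at most one box per frame", {
  sc <- simulateScene(SceneConfig(nIdentities = 1L, nFrames = 10L, seed = 1L))
  d <- sc$dataset
  expect_lte(nDetections(d), 10L)
  expect_equal(unique(identities(d)), 1L)
  expect_length(sc$frames, 10L)
  expect_equal(dim(sc$frames[[1]]), c(96L, 96L, 3L))
})

test_that("the same seed reproduces a scene bit-exactly", {
  cfg <- SceneConfig(nIdentities = 3L, nFrames = 8L, arena = "open", seed = 42L)
  s1 <- simulateScene(cfg)
  s2 <- simulateScene(cfg)
  expect_identical(s1$frames, s2$frames)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeScene(s1, d1); writeScene(s2, d2)
  expect_identical(readLines(file.path(d1, "gt.csv")),
                   readLines(file.path(d2, "gt.csv")))
  expect_identical(readBin(file.path(d1, "frame_000003.png"), "raw", 1e6),
                   readBin(file.path(d2, "frame_000003.png"), "raw", 1e6))
})

test_that("ground truth never repeats an identity within a frame", {
  for (seed in 1:4) {
    sc <- simulateScene(SceneConfig(nIdentities = 6L, nFrames = 25L,
                                    arena = "open", seed = seed))
    for (idx in detectionsByFrame(sc$dataset))
      expect_false(any(duplicated(identities(sc$dataset)[idx])))
  }
})

test_that("ground-truth boxes are clipped to frame and at least 3x3 visible", {
  sc <- simulateScene(SceneConfig(nIdentities = 5L, nFrames = 30L,
                                  arena = "open", seed = 3L))
  b <- boxes(sc$dataset)
  visW <- pmin(b$x + b$w, 96) - pmax(b$x, 0)
  visH <- pmin(b$y + b$h, 96) - pmax(b$y, 0)
  expect_true(all(visW >= 3 & visH >= 3))
  expect_equal(b$w, rep(24, nrow(b)))              # full unoccluded extent
})

test_that("well-separated colours put identity clouds far apart in feature space", {
  sc <- simulateScene(SceneConfig(nIdentities = 3L, nFrames = 30L,
                                  appearanceSeparation = 160,
                                  textureNoise = 5, allowOverlap = FALSE,
                                  seed = 8L))
  td <- featurizeDataset(sc$dataset, sc$frames)
  X <- featureMatrix(td)
  id <- identities(td)
  cent <- t(vapply(1:3, function(k) colMeans(X[id == k, , drop = FALSE]),
                   numeric(54)))
  spread <- mean(vapply(1:3, function(k) {
    mean(sqrt(rowSums(sweep(X[id == k, , drop = FALSE], 2, cent[k, ])^2)))
  }, 0))
  expect_gt(min(dist(cent)), 3 * spread)
})

test_that("scene configs that cannot hold an animal are rejected", {
  expect_error(SceneConfig(frameSize = c(10L, 10L)), "too small")
  expect_error(SceneConfig(nIdentities = 0L), "nIdentities")
  expect_error(SceneConfig(reentryProb = 2), "probability")
})

test_that("unfragmented feature tracks coincide with identities", {
  td <- simulateFeatureTracks(FeatureTrackConfig(nIdentities = 5L,
                                                 nFrames = 30L,
                                                 fragmentation = 1,
                                                 seed = 2L))
  expect_equal(ariScore(tracks(td), identities(td)), 1)
})

test_that("feature-track ground truth and schedule behave", {
  cfg <- FeatureTrackConfig(nIdentities = 4L, nFrames = 20L,
                            fragmentation = 2, seed = 9L)
  td <- simulateFeatureTracks(cfg)
  expect_true(hasFeatures(td))
  for (idx in detectionsByFrame(td))
    expect_false(any(duplicated(identities(td)[idx])))
  # all identities co-occur in every frame: every cross-identity pair is CL
  cl <- trackCLConstraints(td, identities(td))
  expect_equal(nrow(cl), choose(4, 2))
  # determinism
  expect_identical(featureMatrix(simulateFeatureTracks(cfg)), featureMatrix(td))
  expect_error(FeatureTrackConfig(nIdentities = 3L, nSimultaneous = 5L),
               "impossible schedule")
  expect_error(FeatureTrackConfig(fragmentation = 0.5), "fragmentation")
})

test_that("a partial co-occurrence schedule limits per-frame identities", {
  td <- simulateFeatureTracks(FeatureTrackConfig(nIdentities = 6L,
                                                 nFrames = 40L,
                                                 nSimultaneous = 3L,
                                                 fragmentation = 1,
                                                 seed = 4L))
  perFrame <- vapply(detectionsByFrame(td), length, 0L)
  expect_true(all(perFrame <= 3L))
  expect_equal(length(unique(identities(td))), 6L)
})

test_that("track fragmentation degrades the tracks-vs-truth agreement on average", {
  ariAt <- function(fragRate) {
    mean(vapply(1:6, function(s) {
      td <- simulateFeatureTracks(FeatureTrackConfig(nIdentities = 4L,
                                                     nFrames = 30L,
                                                     fragmentation = fragRate,
                                                     seed = s))
      ariScore(tracks(td), identities(td))
    }, 0))
  }
  expect_gt(ariAt(1), ariAt(3))
  expect_gt(ariAt(3), ariAt(8))
})
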