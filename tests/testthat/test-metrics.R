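randomLabels <- function(n, k) sample.int(k, n, replace = TRUE)

test_that("ARI analytic values: identity, one-cluster, all-singletons", {
  expect_equal(ariScore(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(ariScore(c(1, 1, 2, 2), c(7, 7, 3, 3)), 1)   # relabelled identity
  set.seed(1)
  tl <- randomLabels(300, 8)
  expect_equal(ariScore(tl, rep(1L, 300)), 0)               # one cluster
  expect_equal(ariScore(tl, seq_len(300)), 0)               # all singletons
  expect_equal(ariScore(tl, tl), 1)
})

test_that("ARI matches brute-force pair enumeration and is symmetric", {
  set.seed(2)
  for (i in 1:30) {
    n <- sample(5:30, 1)
    tl <- randomLabels(n, sample(2:8, 1))
    al <- randomLabels(n, sample(2:8, 1))
    expect_equal(ariScore(tl, al), oracleAri(tl, al), tolerance = 1e-12)
    expect_equal(ariScore(tl, al), ariScore(al, tl), tolerance = 1e-12)
    # relabelling invariance
    perm <- sample(max(al))
    expect_equal(ariScore(tl, perm[al]), ariScore(tl, al), tolerance = 1e-12)
  }
})

test_that("ARI degenerate-denominator convention", {
  expect_equal(ariScore(rep(1, 5), rep(2, 5)), 1)       # same trivial partition
  expect_equal(ariScore(1:5, 5:1), 1)                   # both all-singletons
  expect_equal(ariScore(rep(1, 5), 1:5), 0)             # different trivial partitions
  expect_error(ariScore(1, 1), "two objects")
  expect_error(ariScore(1:3, 1:4), "equal length")
})

test_that("NMI endpoints and a hand-computed two-class example", {
  tl <- c(1, 1, 2, 2, 3)
  expect_equal(nmiScore(tl, tl), 1)
  expect_equal(nmiScore(tl, c(5, 5, 9, 9, 2)), 1)       # same partition
  expect_equal(nmiScore(tl, rep(1, 5)), 0)              # constant assignment
  # 4 points: tl = (1,1,2,2), al = (1,1,1,2)
  # joint p: (1,1)=1/2, (2,1)=1/4, (2,2)=1/4
  p <- c(0.5, 0.25, 0.25)
  mi <- sum(p * log(p / c(0.5 * 0.75, 0.5 * 0.75, 0.5 * 0.25)))
  h1 <- -sum(c(0.5, 0.5) * log(c(0.5, 0.5)))
  h2 <- -sum(c(0.75, 0.25) * log(c(0.75, 0.25)))
  expect_equal(nmiScore(c(1, 1, 2, 2), c(1, 1, 1, 2)), mi / ((h1 + h2) / 2),
               tolerance = 1e-12)
})

test_that("counting accuracy uses majority many-to-one mapping", {
  expect_equal(countingAccuracy(c(1, 1, 2), c(7, 7, 7)), 2 / 3)
  expect_equal(countingAccuracy(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  set.seed(3)
  tl <- randomLabels(100, 4)
  expect_equal(countingAccuracy(tl, seq_len(100)), 1)   # singletons are perfect
})

test_that("Hungarian accuracy matches the exhaustive-mapping oracle", {
  set.seed(4)
  for (i in 1:30) {
    n <- sample(8:30, 1)
    tl <- randomLabels(n, sample(2:6, 1))
    al <- randomLabels(n, sample(2:6, 1))
    expect_equal(hungarianAccuracy(tl, al),
                 oracleHacc(contingencyTable(tl, al)), tolerance = 1e-12)
    # one-to-one mapping can never beat majority mapping
    expect_lte(hungarianAccuracy(tl, al), countingAccuracy(tl, al) + 1e-12)
  }
})

test_that("all-singleton assignment scores C/N under Hungarian mapping", {
  set.seed(5)
  tl <- c(1:8, randomLabels(691, 8))              # 8 non-empty classes, N = 699
  expect_equal(hungarianAccuracy(tl, seq_along(tl)), 8 / 699)
  expect_equal(round(hungarianAccuracy(tl, seq_along(tl)), 4), 0.0114)
})

test_that("the sanity battery reproduces the analytic degenerate rows", {
  set.seed(6)
  tl <- c(1:8, randomLabels(691, 8))
  bat <- sanityBattery(tl, nClasses = 8, nTracks = 463, seed = 11)
  expect_equal(rownames(bat), c("RL", "SL", "DL", "RA"))
  expect_equal(bat["SL", "ari"], 0)
  expect_equal(bat["SL", "nmi"], 0)
  expect_equal(bat["DL", "ari"], 0)
  expect_equal(bat["DL", "acc"], 1)
  expect_equal(bat["DL", "hacc"], 8 / 699, tolerance = 1e-12)
  expect_lt(abs(bat["RL", "ari"]), 0.05)
  expect_lt(abs(bat["RA", "ari"]), 0.05)
  # reproducible under the same seed
  expect_identical(bat, sanityBattery(tl, 8, 463, seed = 11))
  expect_error(sanityBattery(tl, 8, 1000, seed = 1), "nTracks")
  expect_error(sanityBattery(1:3, 8, 2, seed = 1), "nClasses")
})

test_that("random labellings score near zero ARI across many seeds", {
  # fixed structured truth, so no battery seed can reproduce it by chance
  set.seed(999)
  tl <- sample(rep(1:8, c(120, 90, 80, 75, 70, 65, 55, 45)))
  aris <- vapply(1:20, function(s) sanityBattery(tl, 8, 50, seed = s)["RL", "ari"], 0)
  expect_lt(max(abs(aris)), 0.05)
  expect_lt(abs(mean(aris)), 0.01)
})

test_that("metric report bundles all four scores within their ranges", {
  set.seed(8)
  tl <- randomLabels(120, 5); al <- randomLabels(120, 9)
  rep1 <- metricReport(tl, al)
  expect_named(rep1, c("nmi", "ari", "acc", "hacc"))
  expect_true(rep1$nmi >= 0 && rep1$nmi <= 1)
  expect_true(rep1$ari >= -1 && rep1$ari <= 1)
  expect_true(rep1$acc > 0 && rep1$acc <= 1)
  expect_true(rep1$hacc >= 0 && rep1$hacc <= 1)
})

test_that("incremental Friedman keeps indistinguishable methods together", {
  # identical rank rows: every prefix has p = 1, all methods grouped
  ranks <- matrix(rep(1:4, each = 10), 10, 4)
  ranks[] <- 2.5                                 # fully tied
  r <- incrementalFriedman(ranks)
  expect_equal(r$topGroup, 4L)
  expect_true(all(r$pValues >= 0.999))
})

test_that("strict dominance between two methods is detected", {
  ranks <- cbind(best = rep(1, 15), other = rep(2, 15))
  r <- incrementalFriedman(ranks, alpha = 0.05)
  # exact permutation oracle: under H0 each row's order is a fair coin;
  # seeing 15/15 wins has two-sided probability 2 * 0.5^15
  expect_lt(2 * 0.5^15, 0.05)
  expect_lt(r$pValues[["top2"]], 0.05)
  expect_equal(r$topGroup, 1L)
})

test_that("Friedman p-values equal the closed-form chi-square arithmetic", {
  ranks <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(1, 2, 3), c(1, 3, 2))
  n <- nrow(ranks); k <- 3
  Rj <- colSums(ranks)
  chi2 <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  pHand <- pchisq(chi2, df = k - 1, lower.tail = FALSE)
  r <- incrementalFriedman(ranks, alpha = 1e-9)  # never stop early
  expect_equal(r$pValues[["top3"]], pHand, tolerance = 1e-12)
  expect_error(incrementalFriedman(ranks[, 1, drop = FALSE]), "two methods")
})
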