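# Independent small-scale oracles used to pin down expected values.
# Each is a direct, brute-force restatement of the quantity's definition,
# kept free of the package's own code paths.

# Adjusted Rand by enumerating all C(N,2) object pairs.
oracleAri <- function(tl, al) {
  n <- length(tl)
  a <- b <- c <- d <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      st <- tl[i] == tl[j]; sa <- al[i] == al[j]
      if (st && sa) a <- a + 1
      else if (st && !sa) b <- b + 1
      else if (!st && sa) c <- c + 1
      else d <- d + 1
    }
  }
  tot <- a + b + c + d
  expected <- (a + b) * (a + c) / tot
  maxIdx <- ((a + b) + (a + c)) / 2
  if (abs(maxIdx - expected) < 1e-12) return(if (b + c == 0) 1 else 0)
  (a - expected) / (maxIdx - expected)
}

# Hungarian accuracy by exhaustive search over all one-to-one cluster-to-class
# mappings of a contingency table (smaller dimension <= 6).
oracleHacc <- function(ct) {
  n <- sum(ct)
  if (nrow(ct) > ncol(ct)) ct <- t(ct)
  r <- nrow(ct); c <- ncol(ct)
  best <- 0
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  for (cols in utils::combn(c, r, simplify = FALSE))
    for (p in perms(cols))
      best <- max(best, sum(ct[cbind(seq_len(r), p)]))
  best / n
}

# Maximum total IoU over all one-to-one assignments with pairs below the
# threshold forbidden; enumerates every subset matching (<= 6 x 6).
oracleAssignment <- function(W, threshold) {
  nP <- nrow(W); nC <- ncol(W)
  best <- 0
  recurse <- function(p, usedC, total) {
    if (p > nP) { best <<- max(best, total); return(invisible()) }
    recurse(p + 1L, usedC, total)               # leave row p unmatched
    for (j in seq_len(nC)) {
      if (!usedC[j] && W[p, j] >= threshold)
        recurse(p + 1L, replace(usedC, j, TRUE), total + W[p, j])
    }
  }
  if (nP > 0L && nC > 0L) recurse(1L, rep(FALSE, nC), 0)
  best
}

# IoU of two integer-coordinate boxes by counting unit pixels.
oracleRasterIou <- function(a, b) {
  pix <- function(bx) {
    g <- expand.grid(x = bx[1]:(bx[1] + bx[3] - 1L),
                     y = bx[2]:(bx[2] + bx[4] - 1L))
    paste(g$x, g$y)
  }
  pa <- pix(a); pb <- pix(b)
  length(intersect(pa, pb)) / length(union(pa, pb))
}

# Per-cell mean/std oracle: recompute each grid cell statistic by looping
# over its pixel set one pixel at a time.
oracleGridFeatures <- function(image, box) {
  x0 <- max(0L, floor(box[1])); x1 <- min(dim(image)[2], ceiling(box[1] + box[3]))
  y0 <- max(0L, floor(box[2])); y1 <- min(dim(image)[1], ceiling(box[2] + box[4]))
  cw <- x1 - x0; ch <- y1 - y0
  ce <- x0 + floor((0:3) * cw / 3); re <- y0 + floor((0:3) * ch / 3)
  out <- numeric(0)
  for (gr in 1:3) for (gc in 1:3) for (chan in 1:3) {
    vals <- c()
    for (r in (re[gr] + 1L):re[gr + 1L])
      for (cc in (ce[gc] + 1L):ce[gc + 1L])
        vals <- c(vals, image[r, cc, chan])
    m <- sum(vals) / length(vals)
    out <- c(out, m, sqrt(sum((vals - m)^2) / length(vals)))
  }
  out
}

# Nearest-centroid resubstitution by explicit per-point distance loops.
oracleNearestCentroid <- function(X, labels) {
  cls <- sort(unique(labels))
  cent <- lapply(cls, function(k) colMeans(X[labels == k, , drop = FALSE]))
  pred <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    d <- vapply(cent, function(m) sqrt(sum((X[i, ] - m)^2)), 0)
    pred[i] <- cls[which.min(d)]
  }
  pred
}

# Naive DBSCAN cluster count: connected components of the core-point graph
# (core = at least minPts points within eps, self included). Border points
# do not change the count.
oracleDbscanCount <- function(D, eps, minPts) {
  n <- nrow(D)
  core <- which(rowSums(D <= eps) >= minPts)
  if (length(core) == 0L) return(0L)
  adj <- D[core, core, drop = FALSE] <= eps
  comp <- integer(length(core))
  k <- 0L
  for (s in seq_along(core)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- k
      queue <- c(queue, nb)
    }
  }
  k
}

# A tiny featurized dataset: nTracks tracks over nFrames frames with
# Gaussian features around per-track (or per-group) means.
makeLabelledDataset <- function(means, trackOfDet, frameOfDet, spread = 1,
                                seed = 1L) {
  set.seed(seed)
  n <- length(trackOfDet)
  X <- means[trackOfDet, , drop = FALSE] +
    matrix(rnorm(n * ncol(means), 0, spread), n)
  TrackedDataset(frame = frameOfDet, x = seq_len(n) * 20, y = 0, w = 10,
                 h = 10, track = trackOfDet, features = X)
}
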