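# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each computation so they share no
# code path with the package implementation.

# Brute-force Sauvola: per-pixel loop over replicate-padded square
# windows, population SD, T = m (1 + k (s/R - 1)), foreground < T.
bruteSauvola <- function(img, radius = 25, k = 0.34, R = 128) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ri <- pmin(pmax((i - radius):(i + radius), 1), H)
    ci <- pmin(pmax((j - radius):(j + radius), 1), W)
    win <- img[ri, ci]
    m <- mean(win)
    s <- sqrt(mean((win - m)^2))
    thr <- m * (1 + k * (s / R - 1))
    if (img[i, j] < thr) out[i, j] <- 255
  }
  out
}

# O(n^2) all-pairs nearest-neighbour distances.
bruteNN <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    d <- sqrt((x[-i] - x[i])^2 + (y[-i] - y[i])^2)
    min(d)
  }, 0)
}

# Greedy one-to-one matching of detections to planted cells within a
# tolerance; returns precision/recall/F1 and matched centroid errors.
matchDetections <- function(truth, det, tolPx = 5) {
  if (!nrow(det) || !nrow(truth))
    return(list(f1 = 0, precision = 0, recall = 0, errors = numeric()))
  D <- sqrt(outer(truth$x, det$x, "-")^2 + outer(truth$y, det$y, "-")^2)
  tp <- 0L; errors <- numeric()
  repeat {
    m <- which.min(D)
    if (!length(m) || !is.finite(D[m]) || D[m] > tolPx) break
    i <- (m - 1L) %% nrow(D) + 1L
    j <- (m - 1L) %/% nrow(D) + 1L
    tp <- tp + 1L; errors <- c(errors, D[m])
    D[i, ] <- Inf; D[, j] <- Inf
  }
  precision <- tp / nrow(det); recall <- tp / nrow(truth)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(f1 = f1, precision = precision, recall = recall, errors = errors)
}

# Literal transcription of the Weir & Cockerham (1984) two-population
# variance-components estimator for haploid 0/1 allele counts:
# theta = (MSP - MSG) / (MSP + (nc - 1) MSG).
wcOracle <- function(a1, n1, a2, n2) {
  p1 <- a1 / n1; p2 <- a2 / n2
  ntot <- n1 + n2
  pbar <- (a1 + a2) / ntot
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (2 - 1)
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / ((n1 - 1) + (n2 - 1))
  nc <- (ntot - (n1^2 + n2^2) / ntot) / (2 - 1)
  denom <- msp + (nc - 1) * msg
  if (denom == 0) return(NA_real_)
  (msp - msg) / denom
}

# Per-marker LOD by explicit least-squares fits (lm), the exhaustive
# likelihood-ratio oracle: LOD = (n/2) log10(RSS0/RSS1).
lmLodOracle <- function(X, y) {
  n <- length(y)
  rss0 <- sum((y - mean(y))^2)
  vapply(seq_len(ncol(X)), function(k) {
    fit <- lm(y ~ X[, k])
    rss1 <- sum(residuals(fit)^2)
    (n / 2) * log10(rss0 / rss1)
  }, 0)
}

# Fraction of ground-truth cells present on every day of a series that
# are recovered as single, position-exact tracks.
identityRecovery <- function(cellTable, tracks, nDays) {
  day1 <- cellTable[cellTable$frame == 1, ]
  rec <- 0L
  for (id in day1$id) {
    gt <- cellTable[cellTable$id == id, ]
    gt <- gt[order(gt$frame), ]
    if (nrow(gt) < nDays) next
    tr1 <- tracks$track[tracks$day == 1 &
                          abs(tracks$x - gt$x[1]) < 1e-9 &
                          abs(tracks$y - gt$y[1]) < 1e-9]
    if (!length(tr1)) next
    trk <- tracks[tracks$track == tr1[1], ]
    trk <- trk[order(trk$day), ]
    if (nrow(trk) == nDays && all(abs(trk$x - gt$x) < 1e-9) &&
        all(abs(trk$y - gt$y) < 1e-9))
      rec <- rec + 1L
  }
  c(recovered = rec, total = nrow(day1))
}

# Random 0/255 mask.
randomMask <- function(H, W, p = 0.5, seed = 1) {
  set.seed(seed)
  matrix(ifelse(runif(H * W) < p, 255, 0), H, W)
}
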