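# Registration and frame linking.

test_that("identity point sets register to the identity transform", {
  set.seed(1)
  A <- cbind(runif(40, 0, 300), runif(40, 0, 300))
  fit <- rigidRegister(A, A)
  expect_false(fit$failed)
  expect_lt(abs(fit$theta), 1e-9)
  expect_lt(max(abs(fit$translation)), 1e-9)
  expect_equal(length(fit$inliers), 40L)
})

test_that("planted rigid transforms are recovered to 1e-6", {
  set.seed(2)
  A <- cbind(runif(60, 0, 400), runif(60, 0, 400))
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  B <- t(R %*% t(A)) + matrix(rep(c(5, 3), each = 60), ncol = 2)
  fit <- rigidRegister(A, B)
  expect_false(fit$failed)
  expect_lt(abs(fit$theta - th), 1e-6)
  expect_lt(max(abs(fit$translation - c(5, 3))), 1e-6)
  expect_lt(fit$rmse, 1e-6)
})

test_that("registration survives 50% clutter", {
  set.seed(4)
  A <- cbind(runif(60, 0, 400), runif(60, 0, 400))
  th <- -8 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  B <- t(R %*% t(A)) + matrix(rep(c(-12, 9), each = 60), ncol = 2)
  B[1:30, ] <- cbind(runif(30, 0, 400), runif(30, 0, 400))
  fit <- rigidRegister(A, B)
  expect_false(fit$failed)
  expect_lt(abs(fit$theta - th), 1e-3)
  expect_gte(length(fit$inliers), 30L)
})

test_that("registration failure is flagged, not an error", {
  set.seed(5)
  A <- cbind(runif(20, 0, 100), runif(20, 0, 100))
  B <- cbind(runif(20, 500, 600), runif(20, 500, 600))
  fit <- rigidRegister(A, B, inlierRatio = 0.9, tol = 0.5, maxIter = 50)
  expect_true(fit$failed)
})

test_that("static points yield zero-displacement tracks", {
  set.seed(6)
  P <- data.frame(x = runif(30, 0, 200), y = runif(30, 0, 200))
  frames <- replicate(8, P, simplify = FALSE)
  tr <- linkTracks(frames)
  expect_equal(length(unique(tr$track)), 30L)
  ms <- motionStats(tr, minSpan = 8)
  expect_equal(nrow(ms), 30L)
  expect_true(all(ms$totalDisplacement == 0))
  expect_true(all(ms$medianSpeed == 0))
})

test_that("steps beyond the displacement cap split tracks", {
  f1 <- data.frame(x = 10, y = 10)
  f2 <- data.frame(x = 130, y = 10)    # 120 px in one day: cap exceeded
  tr <- linkTracks(list(f1, f2), maxDisp = 100)
  expect_equal(length(unique(tr$track)), 2L)
  # 90 px in one day links fine
  tr2 <- linkTracks(list(f1, data.frame(x = 100, y = 10)), maxDisp = 100)
  expect_equal(length(unique(tr2$track)), 1L)
  # a one-day gap may be bridged at up to twice the cap
  tr3 <- linkTracks(list(data.frame(x = 0, y = 0), data.frame(x = numeric(),
                                                              y = numeric()),
                         data.frame(x = 150, y = 0)), maxDisp = 100)
  expect_equal(length(unique(tr3$track)), 1L)
})

test_that("linking is stable under detection order and matches optimal on small n", {
  set.seed(7)
  P1 <- data.frame(x = runif(25, 0, 100), y = runif(25, 0, 100))
  P2 <- data.frame(x = P1$x + rnorm(25, 0, 2), y = P1$y + rnorm(25, 0, 2))
  trA <- linkTracks(list(P1, P2))
  perm <- sample(25)
  trB <- linkTracks(list(P1, P2[perm, ]))
  # same partition: each day-2 point joins the same day-1 point
  pairOf <- function(tr) {
    d1 <- tr[tr$day == 1, ]; d2 <- tr[tr$day == 2, ]
    m <- merge(d1, d2, by = "track")
    m <- m[order(m$x.y, m$y.y), c("x.x", "x.y")]
    rownames(m) <- NULL
    m
  }
  expect_equal(pairOf(trA), pairOf(trB))
  # greedy equals the optimal assignment on well-separated points
  trO <- linkTracks(list(P1, P2), method = "optimal")
  expect_equal(pairOf(trA), pairOf(trO))
})

test_that("motion statistics follow the span and speed rules", {
  # a 6-day track is excluded by the >= 7-day rule
  short <- data.frame(track = 1, day = 1:6, x = 1:6, y = 0)
  ms <- motionStats(short)
  expect_equal(nrow(ms), 0L)
  expect_equal(attr(ms, "flag"), "no_qualifying_tracks")
  # straight-line 4 px/day for 9 days: net displacement 32, speed 4
  line <- data.frame(track = 1, day = 1:9, x = 4 * (0:8), y = 0)
  ms2 <- motionStats(line)
  expect_equal(ms2$totalDisplacement, 32)
  expect_equal(ms2$medianSpeed, 4)
  # random-walk steps of fixed length: median speed equals that length
  set.seed(8)
  ang <- runif(11, 0, 2 * pi)
  walk <- data.frame(track = 1, day = 1:12,
                     x = cumsum(c(0, 3 * cos(ang))),
                     y = cumsum(c(0, 3 * sin(ang))))
  expect_equal(motionStats(walk)$medianSpeed, 3)
  # one missing day allowed, two not
  gap1 <- data.frame(track = 1, day = c(1:3, 5:8), x = 0, y = 0)
  expect_equal(nrow(motionStats(gap1)), 1L)
  gap2 <- data.frame(track = 1, day = c(1:3, 6:9), x = 0, y = 0)
  expect_equal(nrow(motionStats(gap2)), 0L)
})

test_that("planted series identities are recovered as single tracks", {
  tot <- c(0, 0)
  for (s in 1:3) {
    sp <- patternSpec("horizontal_stripes", nElements = 2,
                      imageHeight = 256L, imageWidth = 256L, seed = s)
    ser <- genDevelopmentSeries(sp, nDays = 10, appearanceRate = 2,
                                drift = 5, motionMode = "spot_consolidate",
                                lossRate = 0)
    cdf <- cells(ser$truth@cells)
    frames <- lapply(1:10, function(day) cdf[cdf$frame == day, ])
    tr <- linkTracks(frames)
    tot <- tot + identityRecovery(cdf, tr, 10)
  }
  expect_gte(tot[1] / tot[2], 0.95)
})

test_that("consolidating series move more than holding series", {
  sp <- patternSpec("horizontal_stripes", nElements = 2,
                    imageHeight = 256L, imageWidth = 256L, seed = 14)
  med <- sapply(c("spot_consolidate", "stripe_hold"), function(mode) {
    ser <- genDevelopmentSeries(sp, nDays = 10, appearanceRate = 0,
                                drift = 5, motionMode = mode, lossRate = 0)
    cdf <- cells(ser$truth@cells)
    frames <- lapply(1:10, function(day) cdf[cdf$frame == day, ])
    median(motionStats(linkTracks(frames))$totalDisplacement)
  })
  expect_gt(med[["spot_consolidate"]], med[["stripe_hold"]])
})

test_that("cumulative registration brings a drifting series into one frame", {
  set.seed(15)
  P <- cbind(runif(50, 50, 250), runif(50, 50, 250))
  frames <- list(data.frame(x = P[, 1], y = P[, 2]))
  th <- 2 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  cur <- P
  for (k in 2:5) {
    cur <- t(R %*% t(cur)) + matrix(rep(c(3, -2), each = 50), ncol = 2)
    frames[[k]] <- data.frame(x = cur[, 1], y = cur[, 2])
  }
  reg <- registerSeries(frames)
  for (k in 2:5) {
    err <- max(abs(reg[[k]]$x - P[, 1]), abs(reg[[k]]$y - P[, 2]))
    expect_lt(err, 1e-6)
  }
})
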