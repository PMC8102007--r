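# Segmentation: outlier removal, Sauvola thresholding, component filters.

test_that("bright-outlier removal replaces only local outliers", {
  # constant image: unchanged
  img <- matrix(100, 60, 60)
  expect_identical(removeBrightOutliers(img), img)
  # a single 255 pixel on a 100 field becomes the local median
  img[30, 30] <- 255
  out <- removeBrightOutliers(img, t = 50)
  expect_equal(out[30, 30], 100)
  out[30, 30] <- 255
  expect_identical(out, img)          # nothing else changed
  # idempotent once outliers are gone
  fixed <- removeBrightOutliers(img)
  expect_identical(removeBrightOutliers(fixed), fixed)
})

test_that("synthetic glare disks are darkened below 240", {
  out <- genPatternImage(patternSpec("horizontal_stripes",
                                     glareDensity = 0.02, seed = 11))
  red <- out$image[, , 1]
  glare <- red >= 245
  expect_gt(sum(glare), 500)
  fixed <- removeBrightOutliers(red)
  expect_gte(mean(fixed[glare] < 240), 0.95)
})

test_that("Sauvola gives an empty mask on constant images", {
  img <- matrix(180, 64, 64)
  expect_true(all(sauvolaThreshold(img) == 0))
})

test_that("Sauvola detects a small dark disk on a bright field", {
  img <- matrix(200, 80, 80)
  off <- expand.grid(dx = -6:6, dy = -6:6)
  off <- off[off$dx^2 + off$dy^2 <= 36, ]
  img[cbind(40 + off$dy, 40 + off$dx)] <- 20
  mask <- sauvolaThreshold(img, radius = 25, k = 0.34)
  expect_true(all(mask[cbind(40 + off$dy, 40 + off$dx)] == 255))
  # and matches the direct per-pixel evaluation of the formula
  expect_identical(mask, bruteSauvola(img, radius = 25, k = 0.34))
})

test_that("Sauvola equals the brute-force windowed oracle on random images", {
  for (s in 1:10) {
    set.seed(s)
    img <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
    expect_identical(sauvolaThreshold(img, radius = 7),
                     bruteSauvola(img, radius = 7))
  }
})

test_that("melanophore segmentation recovers planted cells", {
  out <- genPatternImage(patternSpec("horizontal_stripes", seed = 21))
  truth <- cells(out$truth)
  truth <- truth[truth$class == "melanophore", ]
  expect_gte(nrow(truth), 60)
  seg <- segmentMelanophores(out$image)
  det <- cells(seg$cells)
  # detected count within +/-10% and centroids within 5 px
  expect_lt(abs(nrow(det) - nrow(truth)) / nrow(truth), 0.10)
  m <- matchDetections(truth, det, tolPx = 5)
  expect_gte(m$recall, 0.9)
  # size band is exact: recompute component areas from the returned mask
  lab <- danioscape:::labelComponents((seg$mask > 0) * 1L)
  if (max(lab) > 0) {
    areas <- tabulate(lab[lab > 0])
    expect_true(all(areas >= 100 & areas <= 1500))
  }
})

test_that("blank images segment to zero cells", {
  out <- genPatternImage(patternSpec("blank", imageHeight = 128L,
                                     imageWidth = 128L))
  expect_equal(nCells(segmentMelanophores(out$image)$cells), 0L)
  expect_equal(nCells(segmentXanthophores(out$image)$cells), 0L)
})

test_that("components outside the size band are excluded", {
  # a disk of ~50 px (below the 100 px melanophore floor) is dropped,
  # a ~200 px disk retained
  img <- array(0, c(200, 200, 3))
  img[, , 1] <- 190; img[, , 2] <- 165; img[, , 3] <- 170
  stamp <- function(im, cx, cy, r, col) {
    off <- expand.grid(dx = -r:r, dy = -r:r)
    off <- off[off$dx^2 + off$dy^2 <= r^2, ]
    for (ch in 1:3) {
      p <- im[, , ch]; p[cbind(cy + off$dy, cx + off$dx)] <- col[ch]
      im[, , ch] <- p
    }
    im
  }
  img <- stamp(img, 50, 50, 4, c(25, 20, 20))    # ~49 px: excluded
  img <- stamp(img, 150, 150, 8, c(25, 20, 20))  # ~197 px: retained
  det <- cells(segmentMelanophores(img)$cells)
  expect_equal(nrow(det), 1L)
  expect_lt(abs(det$x - 149), 2)     # 0-based centroid of the large disk
  # an orange disk of ~300 px is outside the 10-200 xanthophore band
  img2 <- array(0, c(200, 200, 3))
  img2[, , 1] <- 190; img2[, , 2] <- 165; img2[, , 3] <- 170
  img2 <- stamp(img2, 100, 100, 10, c(240, 160, 40))  # ~317 px
  expect_equal(nCells(segmentXanthophores(img2)$cells), 0L)
  img3 <- stamp(img2, 50, 50, 4, c(240, 160, 40))     # ~49 px: retained
  expect_equal(nCells(segmentXanthophores(img3)$cells), 1L)
})

test_that("xanthophore segmentation recovers a planted orange field", {
  out <- genPatternImage(patternSpec("horizontal_stripes", seed = 9))
  truth <- cells(out$truth)
  truth <- truth[truth$class == "xanthophore", ]
  det <- cells(segmentXanthophores(out$image)$cells)
  m <- matchDetections(truth, det, tolPx = 5)
  expect_gte(m$recall, 0.9)
})

test_that("segmentation is translation-equivariant for interior cells", {
  sp <- patternSpec("spots", nElements = 4L, elementWidth = 60,
                    imageHeight = 256L, imageWidth = 256L, seed = 31)
  out <- genPatternImage(sp)
  img <- out$image
  dx <- 7L; dy <- 11L
  shifted <- img
  for (ch in 1:3) {
    p <- matrix(sp@backgroundColor[ch], 256, 256)
    p[(1 + dy):256, (1 + dx):256] <- img[1:(256 - dy), 1:(256 - dx), ch]
    shifted[, , ch] <- p
  }
  d0 <- cells(segmentMelanophores(img)$cells)
  d1 <- cells(segmentMelanophores(shifted)$cells)
  # interior cells (away from all borders by > 40 px)
  keep0 <- d0$x > 40 & d0$x < 256 - 40 - dx & d0$y > 40 & d0$y < 256 - 40 - dy
  int0 <- d0[keep0, ]
  for (i in seq_len(nrow(int0))) {
    dd <- sqrt((d1$x - int0$x[i] - dx)^2 + (d1$y - int0$y[i] - dy)^2)
    expect_lt(min(dd), 1e-6)
  }
})

test_that("glare-free well-spaced fields reach detection F1 >= 0.95", {
  for (s in 1:3) {
    sp <- patternSpec("uniform", imageHeight = 300L, imageWidth = 300L,
                      cellRadius = 8, cellSpacing = 30, jitterSD = 1,
                      seed = 40 + s)
    out <- genPatternImage(sp)
    truth <- cells(out$truth)
    det <- cells(segmentMelanophores(out$image)$cells)
    m <- matchDetections(truth, det, tolPx = 5)
    expect_gte(m$f1, 0.95)
  }
})

test_that("manual corrections drop, add, and invert exactly", {
  cs <- cellSet(id = 1:3, x = c(10, 20, 30), y = c(10, 20, 30),
                area = c(150, 160, 170), class = "melanophore", frame = 0L)
  expect_identical(cells(applyCorrections(cs)), cells(cs))
  # one addition at (10, 10) with d = 15 gains area round(pi * 7.5^2) = 177
  added <- applyCorrections(cs, additions = data.frame(x = 10, y = 10))
  df <- cells(added)
  expect_equal(nrow(df), 4L)
  expect_equal(df$area[4], 177)
  # add then remove the same cell is the identity
  back <- applyCorrections(added, removals = df$id[4])
  expect_identical(cells(back), cells(cs))
  # unknown removal id errors, naming the id
  expect_error(applyCorrections(cs, removals = 99L), "99")
})
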