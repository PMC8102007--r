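# Raster helpers shared by the generator, segmentation, and metrics code.
# Conventions: grey images and masks are H x W matrices (values 0..255,
# masks strictly {0, 255}); RGB images are H x W x 3 arrays; coordinates
# are 0-based pixel centers with x = column, y = row.

# Integer lattice offsets of a Euclidean disk of the given radius.
diskOffsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
}

# Stamp filled disks into a matrix (clipped at borders), returning it.
# xs/ys are 0-based centers; `radii` is recycled over cells.
stampDisks <- function(mat, xs, ys, radii, value) {
  H <- nrow(mat); W <- ncol(mat)
  radii <- rep_len(radii, length(xs))
  for (i in seq_along(xs)) {
    off <- diskOffsets(radii[i])
    rr <- round(ys[i]) + 1L + off$dy
    cc <- round(xs[i]) + 1L + off$dx
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    mat[cbind(rr[ok], cc[ok])] <- value
  }
  mat
}

stampDisksRGB <- function(img, xs, ys, radii, rgb) {
  mask <- stampDisks(matrix(0L, dim(img)[1], dim(img)[2]), xs, ys, radii, 1L)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask == 1L] <- rgb[ch]
    img[, , ch] <- plane
  }
  img
}

#' Validate and coerce a binary mask
#'
#' Checks that a matrix is strictly two-valued on the 0/255 scale (logical
#' and 0/1 inputs are rescaled).
#'
#' @param mask matrix.
#' @return numeric matrix with values in {0, 255}.
#' @export
asMask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (is.logical(mask)) mask <- mask * 255
  u <- unique(as.vector(mask))
  if (all(u %in% c(0, 1))) mask <- mask * 255
  else if (!all(u %in% c(0, 255)))
    stop("mask must be strictly two-valued (0/255)")
  mask
}

#' Rotate a matrix 90 degrees counter-clockwise
#'
#' Convenience for the rotation-duality property of pattern metrics:
#' rotating a mask by 90 degrees exchanges its row and column profiles.
#'
#' @param mat matrix.
#' @return rotated matrix.
#' @export
rotate90 <- function(mat) t(mat)[rev(seq_len(ncol(mat))), , drop = FALSE]

#' Read / write 8-bit images
#'
#' Thin PNG input/output: images are stored in the package's raster
#' convention (0--255 numeric, H x W for grey/masks, H x W x 3 for RGB).
#'
#' @param path file path.
#' @param img matrix or H x W x 3 array with values 0--255.
#' @return `readImagePNG` returns a matrix or array of 0--255 values.
#' @export
readImagePNG <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L && dim(x)[3] >= 3L) x <- x[, , 1:3]
  round(x * 255)
}

#' @rdname readImagePNG
#' @export
writeImagePNG <- function(img, path) {
  png::writePNG(img / 255, target = path)
  invisible(path)
}

# Local mean and standard deviation over square windows of side 2r + 1,
# computed exactly with integral images under replicate padding.
# Returns list(mean, sd); sd uses the population (n) denominator.
localMeanSd <- function(img, radius) {
  H <- nrow(img); W <- ncol(img); r <- as.integer(radius)
  ri <- c(rep(1L, r), seq_len(H), rep(H, r))
  ci <- c(rep(1L, r), seq_len(W), rep(W, r))
  p <- img[ri, ci]
  S <- t(apply(apply(p, 2, cumsum), 1, cumsum))
  S2 <- t(apply(apply(p * p, 2, cumsum), 1, cumsum))
  S <- rbind(0, cbind(0, S)); S2 <- rbind(0, cbind(0, S2))
  n <- (2 * r + 1)^2
  i1 <- seq_len(H); i2 <- i1 + 2L * r + 1L
  j1 <- seq_len(W); j2 <- j1 + 2L * r + 1L
  sm <- S[i2, j2, drop = FALSE] - S[i1, j2, drop = FALSE] -
    S[i2, j1, drop = FALSE] + S[i1, j1, drop = FALSE]
  sq <- S2[i2, j2, drop = FALSE] - S2[i1, j2, drop = FALSE] -
    S2[i2, j1, drop = FALSE] + S2[i1, j1, drop = FALSE]
  m <- sm / n
  v <- pmax(sq / n - m * m, 0)
  list(mean = m, sd = sqrt(v))
}

# 8-connected component labelling (Rcpp union-find). Foreground > 0.
labelComponents <- function(mask) {
  storage.mode(mask) <- "integer"
  .label_components8(mask)
}
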