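# Pigment cell segmentation: bright-outlier removal, Sauvola local
# thresholding, connected components with size-band filters.

#' Remove bright outliers by local-median replacement
#'
#' Each pixel brighter than its local neighbourhood median (square window
#' of side `2 * radius + 1`) by more than `t` grey units is replaced by
#' that median; all other pixels are unchanged. Removes small specular
#' glare (iridophore reflections) while preserving cells; idempotent on
#' outlier-free images.
#'
#' @param img grey matrix, values 0--255.
#' @param radius window radius in px (default 25).
#' @param t brightness-excess threshold in grey units.
#' @return grey matrix of the same size.
#' @export
removeBrightOutliers <- function(img, radius = 25, t = 50) {
  if (radius < 1) stop("radius must be >= 1")
  med <- round(EBImage::medianFilter(img / 255, size = as.integer(radius)) * 255)
  out <- img
  hot <- img > med + t
  out[hot] <- med[hot]
  out
}

#' Sauvola local adaptive threshold (dark-object convention)
#'
#' Per-pixel threshold `T(x, y) = m * (1 + k * (s / R - 1))` with `m`, `s`
#' the mean and standard deviation of the square window of side
#' `2 * radius + 1` centred on the pixel (replicate-padded at borders; the
#' population SD of the window). Pixels strictly below their threshold are
#' foreground (255): the method was designed to pick out numerous dark
#' objects -- text, or here melanophores -- on a light field. On a
#' constant image `s = 0` gives `T = m * (1 - k) < m` everywhere, so the
#' mask is empty.
#'
#' Windows are computed exactly via integral images, so the result is
#' pixel-identical to a brute-force windowed evaluation.
#'
#' @param img grey matrix, values 0--255.
#' @param radius window radius, px.
#' @param k Sauvola sensitivity parameter, 0 < k < 1.
#' @param R dynamic range of the standard deviation (128, the 8-bit
#'   convention).
#' @return binary mask (0/255).
#' @export
sauvolaThreshold <- function(img, radius = 25, k = 0.34, R = 128) {
  if (radius < 1) stop("radius must be >= 1")
  if (k <= 0 || k >= 1) stop("k must be in (0, 1)")
  ls <- localMeanSd(img, radius)
  thr <- ls$mean * (1 + k * (ls$sd / R - 1))
  (img < thr) * 255
}

# Centroids and areas of labelled components; 0-based coordinates.
componentTable <- function(labels) {
  idx <- which(labels > 0L)
  if (!length(idx))
    return(data.frame(label = integer(), x = numeric(), y = numeric(),
                      area = numeric()))
  H <- nrow(labels)
  lab <- labels[idx]
  row0 <- (idx - 1L) %% H          # 0-based row (y)
  col0 <- (idx - 1L) %/% H         # 0-based col (x)
  area <- tabulate(lab)
  data.frame(label = seq_along(area),
             x = as.numeric(tapply(col0, lab, mean)),
             y = as.numeric(tapply(row0, lab, mean)),
             area = as.numeric(area))
}

# shared component extraction + size-band filter
segmentFromGrey <- function(grey, radius, k, R, band, class, frame = 0L) {
  mask <- sauvolaThreshold(grey, radius = radius, k = k, R = R)
  labels <- labelComponents(mask)
  tab <- componentTable(labels)
  keep <- tab$area >= band[1] & tab$area <= band[2]
  tab <- tab[keep, , drop = FALSE]
  outMask <- matrix(0, nrow(grey), ncol(grey))
  if (nrow(tab)) outMask[labels %in% tab$label] <- 255
  cs <- cellSet(id = seq_len(nrow(tab)), x = tab$x, y = tab$y,
                area = tab$area, class = rep(class, nrow(tab)),
                frame = rep(frame, nrow(tab)))
  list(cells = cs, mask = outMask)
}

#' Segment melanophores from an RGB flank image
#'
#' Pipeline: bright-outlier removal on the red channel (which best
#' separates black melanophores from xanthophores and the pinkish skin),
#' Sauvola local thresholding, 8-connected components, and retention of
#' components with area 100--1500 px^2. An image with no dark objects
#' yields an empty cell set, not an error.
#'
#' @param img RGB array H x W x 3, values 0--255.
#' @param radius,k,R Sauvola parameters (see [sauvolaThreshold()]).
#' @param outlierRadius,outlierT bright-outlier removal parameters.
#' @param band retained component area band in px^2.
#' @param frame frame/stage label recorded on the cells.
#' @return list with `cells` (a [CellSet-class]) and `mask` (binary mask
#'   of the retained components).
#' @examples
#' out <- genPatternImage(patternSpec("spots", nElements = 6, seed = 2))
#' seg <- segmentMelanophores(out$image)
#' @export
segmentMelanophores <- function(img, radius = 25, k = 0.34, R = 128,
                                outlierRadius = 25, outlierT = 50,
                                band = c(100, 1500), frame = 0L) {
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("img must be an H x W x 3 RGB array")
  red <- removeBrightOutliers(img[, , 1], radius = outlierRadius, t = outlierT)
  segmentFromGrey(red, radius, k, R, band, "melanophore", frame)
}

#' Segment xanthophores from an RGB flank image
#'
#' Yellow/orange xanthophores have high red and low blue values, so the
#' clipped channel difference `max(red - blue, 0)` is bright over
#' xanthophores and near zero elsewhere; inverting it makes them dark
#' objects for the same Sauvola detector used for melanophores.
#' Components with area 10--200 px^2 are retained.
#'
#' @inheritParams segmentMelanophores
#' @return list with `cells` and `mask` as in [segmentMelanophores()].
#' @export
segmentXanthophores <- function(img, radius = 25, k = 0.34, R = 128,
                                band = c(10, 200), frame = 0L) {
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("img must be an H x W x 3 RGB array")
  dif <- pmax(img[, , 1] - img[, , 3], 0)
  segmentFromGrey(255 - dif, radius, k, R, band, "xanthophore", frame)
}

#' Apply manual corrections to a segmented cell set
#'
#' Improperly segmented cells (e.g. uncontracted melanophores) are
#' corrected by removing listed ids and adding replacement cells rendered
#' as circles of the given diameter: each addition becomes a cell with
#' centroid at the given point and area `round(pi * (d / 2)^2)` px^2
#' (177 px^2 at the default d = 15).
#'
#' @param cells a [CellSet-class].
#' @param additions two-column matrix or data.frame of (x, y) centroids.
#' @param removals integer ids to drop; unknown ids are an error.
#' @param circleDiameter replacement circle diameter, px.
#' @param class class assigned to added cells.
#' @return corrected [CellSet-class].
#' @export
applyCorrections <- function(cells, additions = NULL, removals = integer(),
                             circleDiameter = 15, class = "melanophore") {
  stopifnot(is(cells, "CellSet"))
  df <- cells@cells
  removals <- as.integer(removals)
  if (length(removals)) {
    unknown <- setdiff(removals, df$id)
    if (length(unknown))
      stop(sprintf("cannot remove unknown cell id(s): %s",
                   paste(unknown, collapse = ", ")))
    df <- df[!(df$id %in% removals), , drop = FALSE]
  }
  if (!is.null(additions) && NROW(additions) > 0) {
    additions <- as.data.frame(additions)
    names(additions)[1:2] <- c("x", "y")
    nextId <- if (nrow(df)) max(df$id) + 1L else 1L
    frame <- if (nrow(df)) df$frame[1] else 0L
    add <- data.frame(id = seq.int(nextId, length.out = nrow(additions)),
                      x = additions$x, y = additions$y,
                      area = round(pi * (circleDiameter / 2)^2),
                      class = class, frame = as.integer(frame))
    df <- rbind(df, add)
  }
  new("CellSet", cells = df)
}
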