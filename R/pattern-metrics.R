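# Morphospace statistics: binarized element masks, DV/AP variation,
# log2 ratio, element-level metrics, and phenotype PCA.

#' Build a melanized-element mask from segmented cells
#'
#' Dark pattern elements (entire stripes or spots) are reconstructed from
#' individual melanophores as the union of disks of `radius` px about each
#' melanophore centre; the default 20 px approximates the average
#' nearest-neighbour distance between melanophores, so disks of adjacent
#' cells merge into whole elements. `mode = "expand_blur"` additionally
#' Gaussian-blurs the dilated mask and rethresholds at 50% intensity,
#' filling small gaps similarly to true cell edges.
#'
#' @param cells a [CellSet-class] (melanophores are used).
#' @param dim image dimensions `c(H, W)`.
#' @param radius disk radius, px (> 0).
#' @param mode `"dilate"` or `"expand_blur"`.
#' @param sigma Gaussian blur SD for `expand_blur`, px.
#' @param threshold global re-threshold for `expand_blur` (0--255).
#' @param frame which frame of the cell set to use.
#' @return binary mask (0/255).
#' @export
buildElementMask <- function(cells, dim, radius = 20,
                             mode = c("dilate", "expand_blur"),
                             sigma = 5, threshold = 128, frame = NULL) {
  mode <- match.arg(mode)
  if (radius <= 0) stop("radius must be > 0")
  stopifnot(is(cells, "CellSet"))
  df <- cells@cells
  df <- df[df$class == "melanophore", , drop = FALSE]
  if (!is.null(frame)) df <- df[df$frame == frame, , drop = FALSE]
  mask <- matrix(0, dim[1], dim[2])
  if (nrow(df))
    mask <- stampDisks(mask, df$x, df$y, radius, 255)
  if (mode == "expand_blur" && nrow(df)) {
    sm <- EBImage::gblur(mask / 255, sigma = sigma)
    mask <- (sm * 255 >= threshold) * 255
  }
  mask
}

#' Global threshold to a target foreground fraction
#'
#' Picks the global threshold (foreground = pixels strictly below it, the
#' dark-element convention) whose foreground fraction is nearest the
#' target, ties broken toward the lower threshold. Used to binarize
#' published images that cannot be segmented cell-wise so that they carry
#' similar amounts of segmented pixels as cell-based masks.
#'
#' @param img grey matrix, 0--255.
#' @param targetFraction desired foreground fraction, in (0, 1).
#' @return binary mask (0/255) with attribute `"threshold"`; a constant
#'   image returns all-background with attribute `"flag" = "constant"`
#'   and a warning.
#' @export
binarizeByFraction <- function(img, targetFraction) {
  if (targetFraction <= 0 || targetFraction >= 1)
    stop("targetFraction must be in (0, 1)")
  v <- as.vector(img)
  if (max(v) == min(v)) {
    warning("constant image: returning all-background mask")
    out <- matrix(0, nrow(img), ncol(img))
    attr(out, "flag") <- "constant"
    return(out)
  }
  counts <- tabulate(round(v) + 1L, nbins = 256L)
  frac <- cumsum(counts) / length(v)        # fraction with value < theta
  fracs <- c(0, frac)                       # thresholds theta = 0..256
  best <- which.min(abs(fracs - targetFraction))  # ties -> lower theta
  theta <- best - 1L
  out <- (img < theta) * 255
  attr(out, "threshold") <- theta
  out
}

#' Dorsoventral and anteroposterior pattern variation
#'
#' The DV variation of a binarized pattern is the standard deviation,
#' across rows, of the row-mean grey profile (each row is one
#' anteroposterior transect across the flank); the AP variation is the
#' reciprocal computation over columns. Patterns uniform along an axis
#' approach 0; heterogeneity along an axis raises the value (8-bit grey
#' units, at most 127.5).
#'
#' @param mask binary mask (0/255); logical or 0/1 inputs are rescaled.
#' @param sd `"sample"` (n - 1 denominator, the default) or
#'   `"population"`.
#' @return named numeric `c(dv, ap)`.
#' @export
axisVariation <- function(mask, sd = c("sample", "population")) {
  sdMode <- match.arg(sd)
  mask <- asMask(mask)
  if (nrow(mask) < 2L || ncol(mask) < 2L)
    stop("mask must have at least 2 rows and 2 columns")
  sdFun <- if (sdMode == "sample") stats::sd
  else function(x) sqrt(mean((x - mean(x))^2))
  c(dv = sdFun(rowMeans(mask)), ap = sdFun(colMeans(mask)))
}

#' log2 ratio of DV to AP variation
#'
#' `log2(max(dv, floor) / max(ap, floor))`: positive for horizontally
#' striped patterns, negative for vertically barred ones, near zero for
#' uniform fields. The floor prevents degenerate ratios on near-empty
#' patterns (both-zero inputs give 0).
#'
#' @param dv,ap axis variations in grey units, >= 0.
#' @param floor lower floor in grey units.
#' @return dimensionless log2 ratio.
#' @export
log2Ratio <- function(dv, ap, floor = 0.5) {
  stopifnot(dv >= 0, ap >= 0)
  log2(pmax(dv, floor) / pmax(ap, floor))
}

#' Element-level statistics of a binarized pattern
#'
#' Counts whole melanized elements (8-connected components), their total
#' perimeter (number of 4-connected foreground/background pixel edges,
#' image border included), total area, and coverage (foreground fraction
#' of the ROI).
#'
#' @param mask binary mask (0/255).
#' @return named numeric: `count`, `perimeter`, `area`, `coverage`.
#' @export
elementStats <- function(mask) {
  mask <- asMask(mask)
  fg <- mask > 0
  H <- nrow(fg); W <- ncol(fg)
  area <- sum(fg)
  if (area == 0)
    return(c(count = 0, perimeter = 0, area = 0, coverage = 0))
  labels <- labelComponents(fg * 1L)
  count <- max(labels)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- fg
  core <- pad[2:(H + 1L), 2:(W + 1L)]
  per <- sum(core & !pad[1:H, 2:(W + 1L)]) +
    sum(core & !pad[3:(H + 2L), 2:(W + 1L)]) +
    sum(core & !pad[2:(H + 1L), 1:W]) +
    sum(core & !pad[2:(H + 1L), 3:(W + 2L)])
  c(count = count, perimeter = per, area = area,
    coverage = area / (H * W))
}

#' Full pattern statistics for one individual/stage
#'
#' Convenience wrapper assembling the morphospace and element metrics
#' from an element mask and (optionally) the segmented cells.
#'
#' @param mask binary element mask (0/255).
#' @param cells optional [CellSet-class] for cell counts/densities.
#' @param sd SD convention passed to [axisVariation()].
#' @return one-row data.frame: `dv`, `ap`, `log2Ratio`, `elementCount`,
#'   `elementPerimeter`, `elementArea`, `coverage`, and (when cells are
#'   given) `melanophoreCount`, `xanthophoreCount`, `melanophoreDensity`,
#'   `xanthophoreDensity` (cells/px^2).
#' @export
patternStats <- function(mask, cells = NULL, sd = "sample") {
  av <- axisVariation(mask, sd = sd)
  es <- elementStats(mask)
  out <- data.frame(dv = av[["dv"]], ap = av[["ap"]],
                    log2Ratio = log2Ratio(av[["dv"]], av[["ap"]]),
                    elementCount = es[["count"]],
                    elementPerimeter = es[["perimeter"]],
                    elementArea = es[["area"]],
                    coverage = es[["coverage"]])
  if (!is.null(cells)) {
    df <- cells@cells
    roi <- nrow(mask) * ncol(mask)
    out$melanophoreCount <- sum(df$class == "melanophore")
    out$xanthophoreCount <- sum(df$class == "xanthophore")
    out$melanophoreDensity <- out$melanophoreCount / roi
    out$xanthophoreDensity <- out$xanthophoreCount / roi
  }
  out
}

#' Split each stripe of a stripe mask into aligned equal-area spot chains
#'
#' Replaces every stripe (connected component) with `nSpots` aligned
#' spot-like blocks whose pixel areas sum exactly to the stripe's area:
#' blocks are centred on the stripe's row band, twice its thickness tall
#' (clipped to the image), and evenly spaced along the stripe. This is
#' the stripes-to-spots ontogenetic transformation: it raises AP
#' variation and element count and lowers the log2(DV:AP) ratio while
#' conserving melanized area.
#'
#' @param mask binary stripe mask (0/255).
#' @param nSpots spots per stripe.
#' @return binary mask (0/255) of the spot chains.
#' @export
splitStripesToSpots <- function(mask, nSpots = 6L) {
  mask <- asMask(mask)
  fg <- mask > 0
  H <- nrow(fg); W <- ncol(fg)
  labels <- labelComponents(fg * 1L)
  nComp <- max(labels, 0)
  bands <- lapply(seq_len(nComp), function(l) {
    idx <- which(labels == l)
    rows <- ((idx - 1L) %% H) + 1L
    c(r0 = min(rows), r1 = max(rows), A = length(idx))
  })
  out <- matrix(0, H, W)
  for (l in seq_len(nComp)) {
    b <- bands[[l]]
    A <- b[["A"]]; r0 <- b[["r0"]]; r1 <- b[["r1"]]
    h <- r1 - r0 + 1L
    rc <- (r0 + r1) / 2
    # expand vertically up to 2x, but stay clear of neighbouring stripes
    # so spot chains from different stripes never merge
    gap <- H
    for (m in seq_len(nComp)) {
      if (m == l) next
      bm <- bands[[m]]
      if (bm[["r0"]] > r1) gap <- min(gap, bm[["r0"]] - r1 - 1L)
      if (bm[["r1"]] < r0) gap <- min(gap, r0 - bm[["r1"]] - 1L)
    }
    e <- max(0, min(floor(h / 2), floor(gap / 2) - 1L))
    h2 <- h + 2L * e
    rlo <- max(1L, round(rc - h2 / 2 + 0.5)); rhi <- min(H, rlo + h2 - 1L)
    h2 <- rhi - rlo + 1L
    targets <- rep(A %/% nSpots, nSpots)
    extra <- A %% nSpots
    if (extra) targets[seq_len(extra)] <- targets[seq_len(extra)] + 1L
    segW <- W / nSpots
    for (s in seq_len(nSpots)) {
      a <- targets[s]
      ncolFull <- a %/% h2
      rem <- a %% h2
      width <- ncolFull + (rem > 0L)
      if (width > floor(segW))
        stop("nSpots too small: spot blocks would touch; increase nSpots")
      c0 <- max(1L, round((s - 0.5) * segW - width / 2 + 0.5))
      c0 <- min(c0, W - width + 1L)
      if (ncolFull > 0L)
        out[rlo:rhi, c0:(c0 + ncolFull - 1L)] <- 255
      if (rem > 0L)
        out[rlo:(rlo + rem - 1L), c0 + ncolFull] <- 255
    }
  }
  out
}

#' Principal components of a phenotype table
#'
#' Columns are standardized to zero mean and unit variance and the
#' correlation matrix eigendecomposed, so variance explained sums to 1
#' over all components. Loadings follow the convention that the
#' largest-magnitude loading of each component is positive. Constant
#' columns are dropped with a warning.
#'
#' @param table data.frame of numeric phenotype columns (an `id` column
#'   and non-numeric columns are ignored).
#' @return list with `loadings` (variables x components),
#'   `varianceExplained` (fractions summing to 1), and `scores`.
#' @export
phenotypePCA <- function(table) {
  num <- table[vapply(table, is.numeric, TRUE)]
  num <- num[, setdiff(names(num), "id"), drop = FALSE]
  num <- num[complete.cases(num), , drop = FALSE]
  if (ncol(num) < 2L) stop("need >= 2 complete numeric columns")
  const <- vapply(num, function(x) var(x) == 0, TRUE)
  if (any(const)) {
    warning(sprintf("dropping constant column(s): %s",
                    paste(names(num)[const], collapse = ", ")))
    num <- num[, !const, drop = FALSE]
  }
  p <- prcomp(num, center = TRUE, scale. = TRUE)
  flip <- apply(p$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(p$rotation, 2, flip, `*`)
  scores <- sweep(p$x, 2, flip, `*`)
  ve <- p$sdev^2 / sum(p$sdev^2)
  names(ve) <- colnames(loadings)
  list(loadings = loadings, varianceExplained = ve, scores = scores)
}
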