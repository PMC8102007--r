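# Spatial statistics of segmented cells: nearest-neighbour distances,
# densities, and pigment-area summaries.

#' Nearest-neighbour distances among cells of one class
#'
#' Euclidean distance from each cell to its nearest same-class neighbour.
#' Ties in nearest neighbour are broken toward the lower cell id (the
#' distance is identical either way).
#'
#' @param cells a [CellSet-class] or a data.frame with `id`, `x`, `y`.
#' @param classFilter cell class to use (`NULL` keeps all).
#' @param frame frame to use (`NULL` keeps all).
#' @return data.frame (`id`, `nnId`, `nnDist`), one row per cell; with
#'   fewer than 2 cells an empty data.frame with attribute
#'   `"flag" = "too_few_cells"`.
#' @export
nnDistances <- function(cells, classFilter = "melanophore", frame = NULL) {
  df <- if (is(cells, "CellSet")) cells@cells else as.data.frame(cells)
  if (!is.null(classFilter) && "class" %in% names(df))
    df <- df[df$class == classFilter, , drop = FALSE]
  if (!is.null(frame) && "frame" %in% names(df))
    df <- df[df$frame == frame, , drop = FALSE]
  if (nrow(df) < 2L) {
    out <- data.frame(id = integer(), nnId = integer(), nnDist = numeric())
    attr(out, "flag") <- "too_few_cells"
    return(out)
  }
  ord <- order(df$id)
  df <- df[ord, , drop = FALSE]          # lower ids first for tie-breaks
  D <- as.matrix(dist(cbind(df$x, df$y)))
  diag(D) <- Inf
  j <- apply(D, 1, which.min)            # first (= lowest-id) minimum
  data.frame(id = df$id, nnId = df$id[j],
             nnDist = D[cbind(seq_len(nrow(df)), j)])
}

#' Per-individual cell summary
#'
#' Medians of nearest-neighbour distances and pigment areas, and density
#' relative to the ROI, per cell class. Median nearest-neighbour distance
#' is reported only when a class has ten or more cells (NA below that).
#'
#' @param cells a [CellSet-class].
#' @param roiArea ROI area in px^2 (> 0).
#' @param frame frame to summarize (`NULL` = all cells).
#' @return one-row data.frame: `melanophoreCount`, `melanophoreMedianNN`,
#'   `melanophoreDensity`, `melanophoreMedianArea`, and the xanthophore
#'   analogues.
#' @export
summarizeCells <- function(cells, roiArea, frame = NULL) {
  if (roiArea <= 0) stop("roiArea must be > 0")
  stopifnot(is(cells, "CellSet"))
  df <- cells@cells
  if (!is.null(frame)) df <- df[df$frame == frame, , drop = FALSE]
  one <- function(cls) {
    sub <- df[df$class == cls, , drop = FALSE]
    n <- nrow(sub)
    med <- if (n >= 10L) {
      nn <- nnDistances(sub, classFilter = NULL)
      median(nn$nnDist)
    } else NA_real_
    c(count = n, medianNN = med, density = n / roiArea,
      medianArea = if (n) median(sub$area) else NA_real_)
  }
  m <- one("melanophore"); x <- one("xanthophore")
  data.frame(melanophoreCount = m[["count"]],
             melanophoreMedianNN = m[["medianNN"]],
             melanophoreDensity = m[["density"]],
             melanophoreMedianArea = m[["medianArea"]],
             xanthophoreCount = x[["count"]],
             xanthophoreMedianNN = x[["medianNN"]],
             xanthophoreDensity = x[["density"]],
             xanthophoreMedianArea = x[["medianArea"]])
}
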