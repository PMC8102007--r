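#' Construct a PatternSpec
#'
#' User-facing constructor for [PatternSpec-class]. Defaults render a
#' 512 x 512 px region of interest with three dark elements: melanophores
#' are dark disks (nominal radius 8 px, area ~200 px^2, inside the
#' 100--1500 px^2 retention band used at segmentation), xanthophores are
#' small orange disks (radius 4 px, ~50 px^2, inside the 10--200 px^2
#' band), the background is the light-pink hue of skin and muscle, and
#' glare artifacts are near-white disks emulating iridophore reflections.
#'
#' @param layout pattern class; see [PatternSpec-class].
#' @param imageHeight,imageWidth image size in pixels.
#' @param nElements number of dark elements.
#' @param elementWidth stripe/bar width or spot diameter, px.
#' @param cellRadius nominal melanophore radius, px.
#' @param cellSpacing melanophore lattice spacing within elements, px.
#' @param melanophoreColor,xanthophoreColor,backgroundColor RGB triples.
#' @param glareDensity fraction of pixels under glare disks, in [0, 0.1).
#' @param jitterSD positional jitter SD, px.
#' @param seed integer seed.
#' @return a validated [PatternSpec-class] object.
#' @examples
#' spec <- patternSpec("horizontal_stripes", nElements = 3)
#' @export
patternSpec <- function(layout = c("horizontal_stripes", "vertical_bars",
                                   "spots", "uniform", "blank"),
                        imageHeight = 512L, imageWidth = 512L,
                        nElements = 3L, elementWidth = 60,
                        cellRadius = 8, cellSpacing = 26,
                        melanophoreColor = c(25, 20, 20),
                        xanthophoreColor = c(240, 160, 40),
                        backgroundColor = c(190, 165, 170),
                        glareDensity = 0, jitterSD = 2, seed = 1L) {
  layout <- match.arg(layout)
  new("PatternSpec", layout = layout,
      imageHeight = as.integer(imageHeight), imageWidth = as.integer(imageWidth),
      nElements = as.integer(nElements), elementWidth = as.numeric(elementWidth),
      cellRadius = as.numeric(cellRadius), cellSpacing = as.numeric(cellSpacing),
      melanophoreColor = as.numeric(melanophoreColor),
      xanthophoreColor = as.numeric(xanthophoreColor),
      backgroundColor = as.numeric(backgroundColor),
      glareDensity = as.numeric(glareDensity), jitterSD = as.numeric(jitterSD),
      seed = as.integer(seed))
}

#' Construct a CellSet
#'
#' @param id,x,y,area,class,frame vectors recycled to a common length;
#'   coordinates are 0-based pixel centers (x = column, y = row).
#' @return a [CellSet-class].
#' @export
cellSet <- function(id = integer(), x = numeric(), y = numeric(),
                    area = numeric(), class = character(),
                    frame = integer()) {
  n <- max(length(id), length(x), length(y))
  df <- data.frame(id = as.integer(id),
                   x = as.numeric(x), y = as.numeric(y),
                   area = as.numeric(rep_len(if (length(area)) area else NA_real_, n)),
                   class = rep_len(if (length(class)) class else "melanophore", n),
                   frame = as.integer(rep_len(if (length(frame)) frame else 0L, n)),
                   stringsAsFactors = FALSE)
  if (n == 0L) df <- df[0, ]
  new("CellSet", cells = df)
}

#' @rdname CellSet-class
#' @export
setMethod("cells", "CellSet", function(object) object@cells)

#' @rdname CellSet-class
#' @export
setMethod("nCells", "CellSet", function(object) nrow(object@cells))

#' @rdname GroundTruth-class
#' @export
setMethod("cells", "GroundTruth", function(object) object@cells@cells)

setMethod("show", "CellSet", function(object) {
  df <- object@cells
  cat(sprintf("CellSet: %d cells (%d melanophores, %d xanthophores), %d frame(s)\n",
              nrow(df), sum(df$class == "melanophore"),
              sum(df$class == "xanthophore"),
              length(unique(df$frame))))
})

setMethod("show", "PatternSpec", function(object) {
  cat(sprintf("PatternSpec: %s, %dx%d px, %d element(s) of width %g px, seed %d\n",
              object@layout, object@imageHeight, object@imageWidth,
              object@nElements, object@elementWidth, object@seed))
})

#' Construct a QTLModel
#'
#' @param loci data.frame with columns `chrom`, `pos`, `origin`
#'   (`"hybrid"`/`"pure"`), `effect`; positions must match map markers.
#' @param epistasis optional data.frame with columns `chromI`, `posI`,
#'   `originI`, `chromJ`, `posJ`, `originJ`, `genoI`, `genoJ`, `effect`.
#' @param mean phenotype baseline.
#' @param residSd residual SD (>= 0).
#' @export
qtlModel <- function(loci = data.frame(), epistasis = data.frame(),
                     mean = 0, residSd = 1) {
  new("QTLModel", loci = loci, epistasis = epistasis,
      mean = as.numeric(mean), residSd = as.numeric(residSd))
}

#' @rdname BackcrossFamily-class
#' @export
setMethod("markers", "BackcrossFamily", function(object) object@markers)

#' @rdname genotypes
#' @export
setMethod("genotypes", "BackcrossFamily", function(object, origin = "hybrid") {
  origin <- match.arg(origin, c("hybrid", "pure"))
  if (origin == "hybrid") object@genoHybrid else object@genoPure
})

#' @rdname BackcrossFamily-class
#' @export
setMethod("phenotypes", "BackcrossFamily", function(object) object@phenotypes)

setMethod("show", "BackcrossFamily", function(object) {
  cat(sprintf("BackcrossFamily (%s): %d individuals, %d markers on %d chromosomes, %d phenotype(s)\n",
              object@pedigree, nrow(object@genoHybrid), nrow(object@markers),
              length(unique(object@markers$chrom)),
              ncol(object@phenotypes) - 1L))
})

#' @rdname QTLScanResult-class
#' @export
setMethod("scanTable", "QTLScanResult", function(object) object@scan)

#' @rdname QTLScanResult-class
#' @export
setMethod("peaks", "QTLScanResult", function(object) object@peaks)

#' @rdname QTLScanResult-class
#' @export
setMethod("lodThreshold", "QTLScanResult", function(object) object@threshold)

setMethod("show", "QTLScanResult", function(object) {
  cat(sprintf("QTLScanResult: '%s' on the %s-parent transmission, %d markers, n = %d\n",
              object@phenotype, object@origin, nrow(object@scan), object@n))
  cat(sprintf("  max LOD %.2f at %s; threshold %s\n",
              max(object@scan$lod),
              object@scan$marker[which.max(object@scan$lod)],
              if (is.na(object@threshold)) "unset"
              else sprintf("%.2f (alpha = %g)", object@threshold, object@alpha)))
  if (nrow(object@peaks))
    cat(sprintf("  %d peak(s) above threshold\n", nrow(object@peaks)))
})

#' @rdname FstScanResult-class
#' @export
setMethod("scanTable", "FstScanResult", function(object) object@scan)

setMethod("show", "FstScanResult", function(object) {
  cat(sprintf("FstScanResult (%s transmission): %d markers, groups of %d and %d\n",
              object@origin, nrow(object@scan),
              length(object@groups[[1]]), length(object@groups[[2]])))
  ok <- !is.na(object@scan$fst)
  if (any(ok))
    cat(sprintf("  max F_ST %.3f at %s\n", max(object@scan$fst[ok]),
                object@scan$marker[ok][which.max(object@scan$fst[ok])]))
})

setMethod("show", "TwoLocusResult", function(object) {
  cat(sprintf("TwoLocusResult: F = %.2f (df %g, %g), P = %.3g; interaction contrast %.3g +/- %.3g\n",
              object@fStat, object@df[1], object@df[2], object@pValue,
              object@contrast, object@contrastSE))
  print(object@classes, row.names = FALSE)
})
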