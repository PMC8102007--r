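#' PatternSpec: layout of a synthetic pigment pattern image
#'
#' Describes an idealized flank pattern to be rendered by
#' [genPatternImage()]: the layout class (horizontal stripes, vertical bars,
#' spots, a uniform field, or a blank background), the geometry of the dark
#' elements, the packing of melanophores within them, and imaging nuisance
#' parameters (glare density, positional jitter).
#'
#' @slot layout one of `"horizontal_stripes"`, `"vertical_bars"`, `"spots"`,
#'   `"uniform"`, `"blank"`.
#' @slot imageHeight,imageWidth image dimensions in pixels.
#' @slot nElements number of dark pattern elements (stripes, bars, or spots).
#' @slot elementWidth stripe/bar width or spot diameter, pixels.
#' @slot cellRadius nominal melanophore radius, pixels (rendered radii get a
#'   small Gaussian perturbation).
#' @slot cellSpacing lattice spacing of melanophores within elements, pixels.
#' @slot melanophoreColor,xanthophoreColor,backgroundColor RGB triples 0--255.
#' @slot glareDensity fraction of pixels receiving bright iridophore-like
#'   glare artifacts (near-white disks of radius 1--3 px); must be < 0.1.
#' @slot jitterSD standard deviation of positional noise on cell centers, px.
#' @slot seed integer seed; identical seeds give bit-identical output.
#' @seealso [patternSpec()] for the user constructor.
#' @export
setClass("PatternSpec", representation(
  layout = "character",
  imageHeight = "integer", imageWidth = "integer",
  nElements = "integer", elementWidth = "numeric",
  cellRadius = "numeric", cellSpacing = "numeric",
  melanophoreColor = "numeric", xanthophoreColor = "numeric",
  backgroundColor = "numeric",
  glareDensity = "numeric", jitterSD = "numeric", seed = "integer"
))

.patternLayouts <- c("horizontal_stripes", "vertical_bars", "spots",
                     "uniform", "blank")

setValidity("PatternSpec", function(object) {
  msg <- character()
  if (!(object@layout %in% .patternLayouts))
    msg <- c(msg, sprintf("layout must be one of: %s",
                          paste(.patternLayouts, collapse = ", ")))
  if (object@imageHeight < 1L || object@imageWidth < 1L)
    msg <- c(msg, "image dimensions must be positive")
  if (object@nElements < 0L) msg <- c(msg, "nElements must be >= 0")
  if (object@glareDensity < 0 || object@glareDensity >= 0.1)
    msg <- c(msg, "glareDensity must be in [0, 0.1)")
  for (nm in c("melanophoreColor", "xanthophoreColor", "backgroundColor")) {
    col <- slot(object, nm)
    if (length(col) != 3L || any(col < 0) || any(col > 255))
      msg <- c(msg, sprintf("%s must be an RGB triple in [0, 255]", nm))
  }
  if (object@jitterSD < 0) msg <- c(msg, "jitterSD must be >= 0")
  if (length(msg)) msg else TRUE
})

#' CellSet: detected or ground-truth pigment cells
#'
#' A set of pigment cell records: centroid (0-based pixel coordinates,
#' x = column, y = row), pixel area, cell class, and frame/stage label.
#' The area of a contracted melanophore doubles as its melanin-content
#' proxy.
#'
#' @slot cells data.frame with columns `id` (integer, unique within a
#'   frame), `x`, `y` (numeric, px), `area` (numeric, px^2), `class`
#'   (`"melanophore"` or `"xanthophore"`), `frame` (integer).
#' @seealso [cellSet()], [cells()], [nCells()]
#' @export
setClass("CellSet", representation(cells = "data.frame"))

setValidity("CellSet", function(object) {
  df <- object@cells
  need <- c("id", "x", "y", "area", "class", "frame")
  if (!all(need %in% names(df)))
    return(sprintf("cells must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(df)) {
    if (anyDuplicated(df[, c("id", "frame")]))
      return("cell ids must be unique within a frame")
    if (any(df$area < 0)) return("areas must be >= 0")
    if (!all(df$class %in% c("melanophore", "xanthophore")))
      return("class must be 'melanophore' or 'xanthophore'")
  }
  TRUE
})

#' GroundTruth: planted truth accompanying a synthetic image or series
#'
#' @slot cells a [CellSet-class] of planted cells (all frames of a series).
#' @slot elementMask binary mask (0/255) of the true melanized elements.
#' @slot displacements data.frame (`id`, `day`, `dx`, `dy`) of true per-day
#'   displacement vectors for developmental series (empty for stills).
#' @export
setClass("GroundTruth", representation(
  cells = "CellSet", elementMask = "matrix", displacements = "data.frame"
))

setValidity("GroundTruth", function(object) {
  df <- cells(object@cells)
  H <- nrow(object@elementMask); W <- ncol(object@elementMask)
  if (nrow(df) && H > 0 && W > 0) {
    if (any(df$x < 0 | df$x > W - 1 | df$y < 0 | df$y > H - 1))
      return("every cell centroid must lie inside the image")
    mel <- df[df$class == "melanophore" & df$frame == min(df$frame), ]
    if (nrow(mel)) {
      idx <- cbind(round(mel$y) + 1L, round(mel$x) + 1L)
      if (any(object@elementMask[idx] == 0))
        return("element mask must cover every melanophore centroid")
    }
  }
  TRUE
})

#' QTLModel: generative genetic architecture for a backcross phenotype
#'
#' @slot loci data.frame (`chrom`, `pos`, `origin`, `effect`): additive QTL
#'   placed at map markers; `origin` is `"hybrid"` (alleles differing
#'   between species, transmitted by the F1 hybrid parent) or `"pure"`
#'   (alleles segregating within the pure-species parent).
#' @slot epistasis data.frame (`chromI`, `posI`, `originI`, `chromJ`,
#'   `posJ`, `originJ`, `genoI`, `genoJ`, `effect`): interaction terms
#'   applied only to individuals with the stated two-locus genotype.
#' @slot mean phenotype baseline.
#' @slot residSd residual (environmental) standard deviation, >= 0.
#' @seealso [qtlModel()], [genBackcross()]
#' @export
setClass("QTLModel", representation(
  loci = "data.frame", epistasis = "data.frame",
  mean = "numeric", residSd = "numeric"
))

setValidity("QTLModel", function(object) {
  if (object@residSd < 0) return("residSd must be >= 0")
  if (nrow(object@loci) &&
      !all(object@loci$origin %in% c("hybrid", "pure")))
    return("locus origin must be 'hybrid' or 'pure'")
  TRUE
})

#' BackcrossFamily: genotypes, map, and phenotypes of one backcross family
#'
#' Each backcross individual inherits, per chromosome, one recombinant
#' haplotype from the F1 hybrid parent (0 = pure-species allele, 1 = other
#' species' allele) and one from the pure-species parent (0/1 = which of
#' that parent's two haplotypes), so every marker carries two independent
#' 0/1 transmissions that are scanned separately by origin.
#'
#' @slot markers ordered data.frame (`id`, `chrom`, `pos` in cM).
#' @slot genoHybrid,genoPure n x m integer matrices coded 0/1 with NA for
#'   missing; columns follow `markers`, rownames are individual ids.
#' @slot phenotypes data.frame of named metrics, first column `id`,
#'   rows aligned with genotype rows.
#' @slot pedigree label: `"BC_a"`-like (hybrid sire) or `"BC_b"`-like
#'   (hybrid dam); free text.
#' @export
setClass("BackcrossFamily", representation(
  markers = "data.frame", genoHybrid = "matrix", genoPure = "matrix",
  phenotypes = "data.frame", pedigree = "character"
))

setValidity("BackcrossFamily", function(object) {
  mk <- object@markers
  if (!all(c("id", "chrom", "pos") %in% names(mk)))
    return("markers must have columns id, chrom, pos")
  if (any(is.na(mk$pos))) return("no missing map positions allowed")
  if (is.unsorted(order(mk$chrom, mk$pos)) &&
      any(unlist(tapply(mk$pos, mk$chrom, is.unsorted))))
    return("markers must be ordered by position within chromosomes")
  for (nm in c("genoHybrid", "genoPure")) {
    G <- slot(object, nm)
    if (ncol(G) != nrow(mk))
      return(sprintf("%s must have one column per marker", nm))
    vals <- G[!is.na(G)]
    if (length(vals) && !all(vals %in% c(0L, 1L)))
      return(sprintf("%s codes must be 0, 1, or NA", nm))
  }
  if (nrow(object@phenotypes) != nrow(object@genoHybrid))
    return("phenotype rows must align with genotype rows")
  TRUE
})

#' QTLScanResult: a single-QTL genome scan
#'
#' @slot scan data.frame per marker: `marker`, `chrom`, `pos`, `lod`,
#'   `pctvar` (percent variance explained by that marker alone).
#' @slot phenotype,origin scanned phenotype column and transmitting parent.
#' @slot n number of individuals used.
#' @slot threshold genome-wide LOD threshold (NA until set from
#'   [permutationThreshold()]).
#' @slot alpha significance level the threshold corresponds to.
#' @slot peaks data.frame of peaks above threshold: `marker`, `chrom`,
#'   `pos`, `lod`, `lo`, `hi` (1.5-LOD support interval positions),
#'   `loMarker`, `hiMarker`, `pctvar`.
#' @slot flags character vector of fitting notes (e.g. degenerate fits).
#' @export
setClass("QTLScanResult", representation(
  scan = "data.frame", phenotype = "character", origin = "character",
  n = "integer", threshold = "numeric", alpha = "numeric",
  peaks = "data.frame", flags = "character"
))

setValidity("QTLScanResult", function(object) {
  if (any(object@scan$lod < 0, na.rm = TRUE)) return("LOD must be >= 0")
  if (any(object@scan$pctvar < 0 | object@scan$pctvar > 100, na.rm = TRUE))
    return("pctvar must be within [0, 100]")
  TRUE
})

#' TwoLocusResult: two-locus genotype-class analysis (epistasis test)
#'
#' @slot classes data.frame per genotype combination (`genotype` in
#'   "00","01","10","11"): `n`, `mean`, `sd`, `letter` (compact letter
#'   display from all-pairs Tukey comparisons; classes sharing a letter do
#'   not differ at `alpha`).
#' @slot fStat,pValue,df overall one-way ANOVA across classes.
#' @slot contrast,contrastSE 2x2 interaction contrast
#'   mean(11) - mean(10) - mean(01) + mean(00) and its standard error.
#' @slot transform transform applied to the phenotype before analysis.
#' @slot alpha level used for the letter groupings.
#' @export
setClass("TwoLocusResult", representation(
  classes = "data.frame", fStat = "numeric", pValue = "numeric",
  df = "numeric", contrast = "numeric", contrastSE = "numeric",
  transform = "character", alpha = "numeric"
))

#' FstScanResult: per-marker F_ST between phenotype groups
#'
#' @slot scan data.frame per marker: `marker`, `chrom`, `pos`, `fst`
#'   (Weir--Cockerham estimator; may be slightly negative, NA when
#'   monomorphic), `p` (permutation P), `padj` (Benjamini--Hochberg),
#'   `significant`.
#' @slot groups list of the two individual-id sets compared.
#' @slot origin which transmission's allele codes were scanned.
#' @slot alpha adjusted-P significance level.
#' @export
setClass("FstScanResult", representation(
  scan = "data.frame", groups = "list", origin = "character",
  alpha = "numeric"
))

setValidity("FstScanResult", function(object) {
  if (any(object@scan$fst > 1 + 1e-12, na.rm = TRUE))
    return("F_ST must be <= 1")
  TRUE
})
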