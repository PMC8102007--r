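# Plain-text interchange: cells as CSV, backcross families as TSV/CSV,
# masks and images as PNG (see readImagePNG/writeImagePNG).

#' Read and write cell tables
#'
#' Cells CSV columns: `id`, `x`, `y`, `area`, `class`, `frame`
#' (0-based pixel-center coordinates).
#'
#' @param cells a [CellSet-class].
#' @param path file path.
#' @return `readCellsCSV` returns a [CellSet-class];
#'   `writeCellsCSV` returns the path invisibly.
#' @export
writeCellsCSV <- function(cells, path) {
  stopifnot(is(cells, "CellSet"))
  write.csv(cells@cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCellsCSV
#' @export
readCellsCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  new("CellSet", cells = df)
}

#' Write / read a backcross family as plain text
#'
#' Writes four files under a common prefix: `<prefix>_markers.tsv`
#' (id, chrom, pos), `<prefix>_geno_hybrid.tsv` and
#' `<prefix>_geno_pure.tsv` (individuals x markers, 0/1/NA), and
#' `<prefix>_phenotypes.csv`.
#'
#' @param family a [BackcrossFamily-class].
#' @param prefix path prefix.
#' @return `readBackcrossFamily` returns a [BackcrossFamily-class];
#'   `writeBackcrossFamily` returns the prefix invisibly.
#' @export
writeBackcrossFamily <- function(family, prefix) {
  stopifnot(is(family, "BackcrossFamily"))
  write.table(family@markers, paste0(prefix, "_markers.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  for (nm in c("Hybrid", "Pure")) {
    G <- slot(family, paste0("geno", nm))
    write.table(data.frame(id = rownames(G), G, check.names = FALSE),
                paste0(prefix, "_geno_", tolower(nm), ".tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  }
  write.csv(family@phenotypes, paste0(prefix, "_phenotypes.csv"),
            row.names = FALSE)
  invisible(prefix)
}

#' @rdname writeBackcrossFamily
#' @param pedigree family label recorded on the read object.
#' @export
readBackcrossFamily <- function(prefix, pedigree = "BC") {
  mk <- read.delim(paste0(prefix, "_markers.tsv"), stringsAsFactors = FALSE)
  readG <- function(which) {
    df <- read.delim(paste0(prefix, "_geno_", which, ".tsv"),
                     check.names = FALSE, stringsAsFactors = FALSE)
    G <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(G) <- "integer"
    rownames(G) <- df$id
    G
  }
  ph <- read.csv(paste0(prefix, "_phenotypes.csv"), stringsAsFactors = FALSE)
  new("BackcrossFamily", markers = mk, genoHybrid = readG("hybrid"),
      genoPure = readG("pure"), phenotypes = ph, pedigree = pedigree)
}

#' Plot a genome scan
#'
#' LOD or F_ST values per marker, concatenated across chromosomes with
#' alternating shading and the threshold as a dashed line.
#'
#' @param scan a [QTLScanResult-class] or [FstScanResult-class].
#' @param ... passed to [graphics::plot()].
#' @export
plotScan <- function(scan, ...) {
  df <- scanTable(scan)
  stat <- if ("lod" %in% names(df)) df$lod else df$fst
  lab <- if ("lod" %in% names(df)) "LOD" else expression(F[ST])
  idx <- seq_len(nrow(df))
  graphics::plot(idx, stat, type = "n", xlab = "marker (by chromosome)",
                 ylab = lab, ...)
  chroms <- unique(df$chrom)
  for (i in seq_along(chroms)) {
    sel <- df$chrom == chroms[i]
    if (i %% 2 == 0)
      graphics::rect(min(idx[sel]) - 0.5, graphics::par("usr")[3],
                     max(idx[sel]) + 0.5, graphics::par("usr")[4],
                     col = grDevices::grey(0.93), border = NA)
  }
  graphics::points(idx, stat, pch = 16, cex = 0.5,
                   col = ifelse(df$chrom %% 2 == 0, "steelblue4", "grey25"))
  if (is(scan, "QTLScanResult") && !is.na(scan@threshold))
    graphics::abline(h = scan@threshold, lty = 2)
  invisible(NULL)
}
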