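# Backcross mapping: Haley-Knott single-QTL LOD scans, permutation
# thresholds, 1.5-LOD support intervals, variance explained, two-locus
# epistasis analysis, and extreme-phenotype F_ST scans.

# Expected genotype matrix for one origin: observed 0/1 where genotyped,
# conditional expectation from flanking markers under Haldane where
# missing (this is what makes the regression Haley-Knott rather than
# marker regression). Returns a numeric matrix without NAs.
expectedGenotypes <- function(family, origin = "hybrid") {
  G <- genotypes(family, origin)
  if (!anyNA(G)) return(G + 0)
  mk <- markers(family)
  X <- G + 0
  trans <- function(g, r) if (g == 1) 1 - r else r  # P(g -> 1)
  for (ch in unique(mk$chrom)) {
    cols <- which(mk$chrom == ch)
    pos <- mk$pos[cols]
    sub <- G[, cols, drop = FALSE]
    nas <- which(is.na(sub), arr.ind = TRUE)
    if (!nrow(nas)) next
    for (row in unique(nas[, 1])) {
      obs <- which(!is.na(sub[row, ]))
      for (k in nas[nas[, 1] == row, 2]) {
        lft <- obs[obs < k]; rgt <- obs[obs > k]
        l <- if (length(lft)) max(lft) else NA
        r <- if (length(rgt)) min(rgt) else NA
        p <- if (is.na(l) && is.na(r)) 0.5
        else if (is.na(r)) trans(sub[row, l], haldane(pos[k] - pos[l]))
        else if (is.na(l)) trans(sub[row, r], haldane(pos[r] - pos[k]))
        else {
          pl1 <- trans(sub[row, l], haldane(pos[k] - pos[l]))
          pr1 <- trans(sub[row, r], haldane(pos[r] - pos[k]))
          # note trans is symmetric: P(1 -> g_r) = P(g_r -> 1)
          pl1 * pr1 / (pl1 * pr1 + (1 - pl1) * (1 - pr1))
        }
        X[row, cols[k]] <- p
      }
    }
  }
  X
}

# Vectorized per-marker LOD from a (possibly imputed) genotype matrix.
# LOD_k = (n/2) log10(RSS0 / RSS1) = -(n/2) log10(1 - r_k^2).
lodVector <- function(X, y, cap = 300) {
  n <- length(y)
  sdx <- apply(X, 2, sd)
  r2 <- rep(0, ncol(X))
  ok <- sdx > 0
  if (any(ok)) r2[ok] <- as.vector(cor(X[, ok, drop = FALSE], y))^2
  lod <- -(n / 2) * log10(pmax(1 - r2, 0))
  degenerate <- !is.finite(lod) | lod > cap
  lod[degenerate] <- cap
  attr(lod, "degenerate") <- degenerate
  lod
}

#' Single-QTL genome scan by Haley-Knott regression
#'
#' At each marker the phenotype is regressed on the genotype probability
#' for the selected transmitting parent: the observed 0/1 code where
#' genotyped, the conditional expectation from flanking markers under the
#' Haldane mapping function where missing. The LOD score is
#' `(n/2) * log10(RSS0 / RSS1)` with `RSS0` the intercept-only residual
#' sum of squares. Degenerate perfect fits are capped at `cap` and
#' flagged. A constant phenotype yields an all-zero scan with a flag.
#'
#' Scanning the hybrid-parent transmission maps alleles differing between
#' the two species; scanning the pure-parent transmission maps variation
#' segregating within the pure-species stock.
#'
#' @param family a [BackcrossFamily-class].
#' @param phenotype name of the phenotype column.
#' @param origin `"hybrid"` or `"pure"`.
#' @param dropMissing drop markers with any missing genotype instead of
#'   imputing them.
#' @param cap LOD cap for degenerate fits.
#' @return a [QTLScanResult-class] (threshold unset; see
#'   [permutationThreshold()] and [findPeaks()]).
#' @export
lodScan <- function(family, phenotype, origin = c("hybrid", "pure"),
                    dropMissing = FALSE, cap = 300) {
  origin <- match.arg(origin)
  y <- phenotypes(family)[[phenotype]]
  if (is.null(y)) stop(sprintf("no phenotype column '%s'", phenotype))
  keep <- !is.na(y)
  if (sum(keep) < 20L) stop("need >= 20 individuals with phenotype")
  mk <- markers(family)
  if (dropMissing) {
    full <- !apply(is.na(genotypes(family, origin)), 2, any)
    X <- genotypes(family, origin)[keep, full, drop = FALSE] + 0
    mk <- mk[full, , drop = FALSE]
  } else {
    X <- expectedGenotypes(family, origin)[keep, , drop = FALSE]
  }
  y <- y[keep]
  flags <- character()
  if (sd(y) == 0) {
    lod <- rep(0, ncol(X)); r2 <- rep(0, ncol(X))
    flags <- "constant_phenotype"
  } else {
    lod <- lodVector(X, y, cap = cap)
    r2 <- 1 - 10^(-2 * lod / length(y))
    if (any(attr(lod, "degenerate"))) flags <- "degenerate_fit_capped"
  }
  scan <- data.frame(marker = mk$id, chrom = mk$chrom, pos = mk$pos,
                     lod = as.numeric(lod), pctvar = 100 * r2,
                     stringsAsFactors = FALSE)
  new("QTLScanResult", scan = scan, phenotype = phenotype, origin = origin,
      n = length(y), threshold = NA_real_, alpha = NA_real_,
      peaks = data.frame(), flags = flags)
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes phenotype labels, rescans, and records the genome-wide
#' maximum LOD of each permutation; the threshold is the empirical
#' `1 - alpha` quantile (type-7 interpolation) of those maxima. Fixed
#' seeds give identical thresholds.
#'
#' @inheritParams lodScan
#' @param nPerm number of permutations (>= 100).
#' @param alpha genome-wide significance level.
#' @param seed RNG seed.
#' @return threshold in LOD units, with attribute `"maxima"`.
#' @export
permutationThreshold <- function(family, phenotype,
                                 origin = c("hybrid", "pure"),
                                 nPerm = 1000L, alpha = 0.05, seed = 1L,
                                 dropMissing = FALSE) {
  origin <- match.arg(origin)
  if (nPerm < 100L) stop("nPerm must be >= 100")
  y <- phenotypes(family)[[phenotype]]
  keep <- !is.na(y)
  if (dropMissing) {
    full <- !apply(is.na(genotypes(family, origin)), 2, any)
    X <- genotypes(family, origin)[keep, full, drop = FALSE] + 0
  } else {
    X <- expectedGenotypes(family, origin)[keep, , drop = FALSE]
  }
  y <- y[keep]
  withSeed(seed, {
    n <- length(y)
    Yp <- vapply(seq_len(nPerm), function(i) y[sample.int(n)], numeric(n))
    sdx <- apply(X, 2, sd)
    Xok <- X[, sdx > 0, drop = FALSE]
    R2 <- cor(Xok, Yp)^2
    maxima <- -(n / 2) * log10(pmax(1 - apply(R2, 2, max), 1e-300))
    thr <- as.numeric(quantile(maxima, 1 - alpha, type = 7))
    attr(thr, "maxima") <- maxima
    thr
  })
}

#' 1.5-LOD support interval around a peak
#'
#' The widest contiguous marker interval around the peak, on the peak's
#' chromosome, where LOD stays within `drop` of the peak, extended one
#' marker beyond on each side when available (a conservative convention).
#' Peaks at chromosome ends give one-sided intervals.
#'
#' @param scan a [QTLScanResult-class].
#' @param peakMarker marker id of the peak.
#' @param drop LOD drop defining the interval.
#' @return data.frame with `loMarker`, `hiMarker`, `lo`, `hi` (positions).
#' @export
lodInterval <- function(scan, peakMarker, drop = 1.5) {
  df <- scanTable(scan)
  pk <- which(df$marker == peakMarker)
  if (!length(pk)) stop(sprintf("marker '%s' not in scan", peakMarker))
  ch <- df$chrom[pk]
  sub <- df[df$chrom == ch, , drop = FALSE]
  k <- which(sub$marker == peakMarker)
  thr <- sub$lod[k] - drop
  lo <- k; while (lo > 1L && sub$lod[lo - 1L] >= thr) lo <- lo - 1L
  hi <- k; while (hi < nrow(sub) && sub$lod[hi + 1L] >= thr) hi <- hi + 1L
  lo <- max(1L, lo - 1L)            # one marker beyond, when available
  hi <- min(nrow(sub), hi + 1L)
  data.frame(loMarker = sub$marker[lo], hiMarker = sub$marker[hi],
             lo = sub$pos[lo], hi = sub$pos[hi], stringsAsFactors = FALSE)
}

#' Percent phenotypic variance explained by one marker
#'
#' `100 * (1 - RSS1 / RSS0)` from the single-marker Haley-Knott
#' regression.
#'
#' @inheritParams lodScan
#' @param marker marker id.
#' @return percent in [0, 100].
#' @export
varianceExplained <- function(family, phenotype, marker,
                              origin = c("hybrid", "pure")) {
  origin <- match.arg(origin)
  y <- phenotypes(family)[[phenotype]]
  keep <- !is.na(y)
  X <- expectedGenotypes(family, origin)[keep, , drop = FALSE]
  k <- which(markers(family)$id == marker)
  if (!length(k)) stop(sprintf("marker '%s' not on map", marker))
  x <- X[, k]; y <- y[keep]
  if (sd(x) == 0 || sd(y) == 0) return(0)
  100 * cor(x, y)^2
}

#' Attach threshold and peaks to a scan
#'
#' Finds, per chromosome, the maximum-LOD marker at or above the
#' threshold, its 1.5-LOD support interval, and its percent variance
#' explained.
#'
#' @param scan a [QTLScanResult-class].
#' @param threshold genome-wide LOD threshold (e.g. from
#'   [permutationThreshold()]).
#' @param alpha the level the threshold corresponds to (annotation only).
#' @param drop LOD drop for support intervals.
#' @return the scan with `threshold` and `peaks` filled in.
#' @export
findPeaks <- function(scan, threshold, alpha = 0.05, drop = 1.5) {
  df <- scanTable(scan)
  pks <- list()
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    k <- which.max(sub$lod)
    if (sub$lod[k] >= threshold) {
      iv <- lodInterval(scan, sub$marker[k], drop = drop)
      pks[[length(pks) + 1L]] <- data.frame(
        marker = sub$marker[k], chrom = ch, pos = sub$pos[k],
        lod = sub$lod[k], lo = iv$lo, hi = iv$hi,
        loMarker = iv$loMarker, hiMarker = iv$hiMarker,
        pctvar = sub$pctvar[k], stringsAsFactors = FALSE)
    }
  }
  scan@threshold <- as.numeric(threshold)
  scan@alpha <- alpha
  scan@peaks <- if (length(pks)) do.call(rbind, pks) else data.frame()
  scan
}

# Compact letter display: maximal cliques of the not-significantly-
# different graph, ordered by their best group mean, lettered a, b, ...
letterGroups <- function(nsd, means) {
  g <- igraph::graph_from_adjacency_matrix(nsd, mode = "undirected",
                                           diag = FALSE)
  cl <- igraph::max_cliques(g)
  ord <- order(vapply(cl, function(x) -max(means[as.integer(x)]), 0))
  cl <- cl[ord]
  letters_out <- rep("", length(means))
  for (i in seq_along(cl)) {
    mem <- as.integer(cl[[i]])
    letters_out[mem] <- paste0(letters_out[mem], letters[i])
  }
  letters_out
}

#' Two-locus genotype-class analysis (epistasis test)
#'
#' Compares the four two-locus genotype combinations by one-way analysis
#' of variance plus the 2 x 2 interaction contrast
#' `mean(11) - mean(10) - mean(01) + mean(00)` (zero under additivity),
#' with all-pairs studentized-range (Tukey) comparisons summarized as
#' compact letter groupings: classes sharing a letter do not differ at
#' `alpha`. A natural-log transform is available for count phenotypes
#' whose residual variance grows with the mean.
#'
#' @param family a [BackcrossFamily-class].
#' @param phenotype phenotype column name.
#' @param markerI,markerJ marker ids of the two loci.
#' @param originI,originJ transmitting parent of each locus.
#' @param transform `"none"` or `"log"` (natural log).
#' @param alpha level for the letter groupings.
#' @return a [TwoLocusResult-class].
#' @export
twoLocusAnalysis <- function(family, phenotype, markerI, markerJ,
                             originI = "hybrid", originJ = "pure",
                             transform = c("none", "log"), alpha = 0.05) {
  transform <- match.arg(transform)
  mk <- markers(family)
  ki <- which(mk$id == markerI); kj <- which(mk$id == markerJ)
  if (!length(ki) || !length(kj)) stop("both markers must be on the map")
  gi <- genotypes(family, originI)[, ki]
  gj <- genotypes(family, originJ)[, kj]
  y <- phenotypes(family)[[phenotype]]
  keep <- !is.na(gi) & !is.na(gj) & !is.na(y)
  gi <- gi[keep]; gj <- gj[keep]; y <- y[keep]
  if (transform == "log") {
    if (any(y <= 0)) stop("log transform requires positive phenotype values")
    y <- log(y)
  }
  cls <- factor(paste0(gi, gj), levels = c("00", "01", "10", "11"))
  present <- levels(cls)[table(cls) > 0]
  if (length(present) < 4L)
    warning(sprintf("empty genotype class(es): %s; analysis on remaining classes",
                    paste(setdiff(levels(cls), present), collapse = ", ")))
  clsUse <- factor(as.character(cls), levels = present)
  fit <- aov(y ~ clsUse)
  an <- anova(fit)
  tt <- tapply(y, clsUse, mean)
  nn <- as.integer(table(clsUse))
  ss <- tapply(y, clsUse, sd)
  mse <- an[["Mean Sq"]][2]
  # letter groupings from all-pairs Tukey comparisons
  letter <- rep("a", length(present))
  if (length(present) > 1L) {
    tk <- TukeyHSD(fit)$clsUse
    nsd <- matrix(TRUE, length(present), length(present),
                  dimnames = list(present, present))
    for (rn in rownames(tk)) {
      pair <- strsplit(rn, "-", fixed = TRUE)[[1]]
      same <- tk[rn, "p adj"] > alpha
      nsd[pair[1], pair[2]] <- nsd[pair[2], pair[1]] <- same
    }
    letter <- letterGroups(nsd, as.numeric(tt))
  }
  contrast <- if (all(c("00", "01", "10", "11") %in% present))
    unname(tt["11"] - tt["10"] - tt["01"] + tt["00"]) else NA_real_
  contrastSE <- if (is.na(contrast)) NA_real_ else sqrt(mse * sum(1 / nn))
  classes <- data.frame(genotype = present, n = nn,
                        mean = as.numeric(tt), sd = as.numeric(ss),
                        letter = letter, stringsAsFactors = FALSE)
  new("TwoLocusResult", classes = classes,
      fStat = an[["F value"]][1], pValue = an[["Pr(>F)"]][1],
      df = an[["Df"]], contrast = contrast, contrastSE = contrastSE,
      transform = transform, alpha = alpha)
}

#' Select phenotypic extremes
#'
#' The `ceiling(fraction * n)` lowest and highest individuals by the
#' phenotype; boundary ties are broken by individual id. With the default
#' 3.5% tails, 457 siblings give 16 individuals per tail (the fraction is
#' followed literally even where a study design quotes a slightly larger
#' per-tail count).
#'
#' @param values numeric phenotype vector.
#' @param ids individual ids (default positional indices).
#' @param fraction tail fraction, in (0, 0.5); an error if the two tails
#'   would overlap.
#' @return list with `low` and `high` id sets and `k` per-tail count.
#' @export
selectExtremes <- function(values, ids = seq_along(values),
                           fraction = 0.035) {
  if (fraction <= 0 || fraction >= 0.5)
    stop("fraction must be in (0, 0.5)")
  n <- length(values)
  k <- ceiling(fraction * n)
  if (2 * k > n) stop("tails would overlap: fraction too large for n")
  lowOrd <- order(values, ids)
  highOrd <- order(-values, ids)
  list(low = ids[lowOrd[seq_len(k)]], high = ids[highOrd[seq_len(k)]],
       k = k)
}

# Weir-Cockerham (1984) two-population theta for 0/1 allele codes
# (one transmitted allele per individual). Vectorized over markers.
# p1/p2: allele-1 frequencies; n1/n2: non-missing allele counts.
wcTheta <- function(p1, n1, p2, n2) {
  N <- n1 + n2
  r <- 2
  pbar <- (n1 * p1 + n2 * p2) / N
  msp <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / (r - 1)
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / ((n1 - 1) + (n2 - 1))
  nc <- (N - (n1^2 + n2^2) / N) / (r - 1)
  theta <- (msp - msg) / (msp + (nc - 1) * msg)
  theta[msp + (nc - 1) * msg == 0] <- NA_real_   # monomorphic
  theta
}

#' Genome-wide F_ST scan between phenotype groups
#'
#' Per-marker two-population F_ST by the Weir--Cockerham (1984)
#' variance-components estimator applied to the 0/1 allele codes of the
#' chosen transmission, between two disjoint sets of individuals (e.g.
#' the striped and spotted extremes of a backcross sibship). Per-marker
#' significance is assessed by permuting group labels, with
#' Benjamini--Hochberg adjustment across markers. The estimator may be
#' slightly negative under no differentiation; values are not clamped.
#' Monomorphic markers are reported as NA.
#'
#' @param family a [BackcrossFamily-class].
#' @param groups list of two disjoint id vectors (each >= 2 individuals),
#'   e.g. from [selectExtremes()].
#' @param origin which transmission's allele codes to scan.
#' @param nPerm permutations for per-marker P values (0 skips them).
#' @param alpha adjusted-P significance level.
#' @param seed RNG seed for the permutations.
#' @return an [FstScanResult-class].
#' @export
fstScan <- function(family, groups, origin = c("hybrid", "pure"),
                    nPerm = 1000L, alpha = 0.01, seed = 1L) {
  origin <- match.arg(origin)
  stopifnot(length(groups) == 2L)
  g1 <- groups[[1]]; g2 <- groups[[2]]
  if (length(intersect(g1, g2))) stop("groups must be disjoint")
  if (length(g1) < 2L || length(g2) < 2L)
    stop("each group needs >= 2 individuals")
  G <- genotypes(family, origin)
  ids <- phenotypes(family)$id
  i1 <- match(g1, ids); i2 <- match(g2, ids)
  if (anyNA(i1) || anyNA(i2)) stop("unknown individual id in groups")
  mk <- markers(family)
  fstOf <- function(i1, i2) {
    G1 <- G[i1, , drop = FALSE]; G2 <- G[i2, , drop = FALSE]
    n1 <- colSums(!is.na(G1)); n2 <- colSums(!is.na(G2))
    p1 <- colMeans(G1, na.rm = TRUE); p2 <- colMeans(G2, na.rm = TRUE)
    bad <- n1 < 2 | n2 < 2
    th <- wcTheta(p1, n1, p2, n2)
    th[bad] <- NA_real_
    th
  }
  obs <- fstOf(i1, i2)
  p <- padj <- rep(NA_real_, length(obs))
  if (nPerm > 0L) {
    withSeed(seed, {
      all_i <- c(i1, i2)
      k1 <- length(i1)
      count <- rep(0L, length(obs))
      for (b in seq_len(nPerm)) {
        sh <- sample(all_i)
        th <- fstOf(sh[seq_len(k1)], sh[-seq_len(k1)])
        count <- count + as.integer(!is.na(th) & !is.na(obs) & th >= obs)
      }
      p <- ifelse(is.na(obs), NA_real_, (1 + count) / (nPerm + 1))
    })
    padj <- p.adjust(p, method = "BH")
  }
  scan <- data.frame(marker = mk$id, chrom = mk$chrom, pos = mk$pos,
                     fst = obs, p = p, padj = padj,
                     significant = !is.na(padj) & padj <= alpha,
                     stringsAsFactors = FALSE)
  new("FstScanResult", scan = scan, groups = list(g1, g2), origin = origin,
      alpha = alpha)
}
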