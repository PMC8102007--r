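# Simulated backcross families: recombinant gametes under the Haldane
# (no-interference) mapping function, and phenotypes from an additive +
# epistatic QTL model with Gaussian residuals.

#' Evenly spaced marker map
#'
#' @param nChrom number of chromosomes (the Danio karyotype has 25).
#' @param markersPerChrom markers per chromosome.
#' @param chromLength chromosome length in cM.
#' @return data.frame (`id`, `chrom`, `pos`), ordered within chromosomes.
#' @export
makeMarkerMap <- function(nChrom = 25L, markersPerChrom = 10L,
                          chromLength = 100) {
  pos <- seq(0, chromLength, length.out = markersPerChrom)
  do.call(rbind, lapply(seq_len(nChrom), function(ch)
    data.frame(id = sprintf("c%dm%d", ch, seq_len(markersPerChrom)),
               chrom = ch, pos = pos)))
}

#' Haldane map distance to recombination fraction
#'
#' r = (1 - exp(-2 d / 100)) / 2 for a distance `d` in centimorgans; the
#' no-interference model, chosen for its closed-form oracle.
#'
#' @param d map distance in cM.
#' @return recombination fraction in [0, 0.5).
#' @export
haldane <- function(d) 0.5 * (1 - exp(-2 * d / 100))

# Simulate n gametes along one ordered chromosome map (positions in cM).
# Returns an n x m 0/1 matrix; adjacent-marker switches occur with the
# Haldane recombination fraction, independently across intervals.
simulateGametes <- function(n, pos) {
  m <- length(pos)
  G <- matrix(0L, n, m)
  G[, 1] <- as.integer(runif(n) < 0.5)
  if (m > 1L) for (k in 2:m) {
    r <- haldane(pos[k] - pos[k - 1])
    sw <- runif(n) < r
    G[, k] <- ifelse(sw, 1L - G[, k - 1], G[, k - 1])
  }
  G
}

# index of the marker matching (chrom, pos); error when absent
markerIndexAt <- function(map, chrom, pos) {
  i <- which(map$chrom == chrom & abs(map$pos - pos) < 1e-9)
  if (!length(i))
    stop(sprintf("locus chr%s:%s is not on the marker map", chrom, pos))
  i[1]
}

#' Simulate a backcross family
#'
#' Gametes of the two transmitting parents are simulated independently by
#' recombination under the Haldane mapping function; each backcross
#' individual receives one 0/1-coded haplotype from the hybrid parent
#' (0 = pure-species allele, 1 = the other species' allele) and one from
#' the pure-species parent (0/1 = which of that parent's two haplotypes),
#' so both interspecific and intraspecific variation are simulable. The
#' phenotype is `mean + sum(additive effects) + epistatic terms +
#' N(0, residSd)`.
#'
#' @param n number of individuals.
#' @param map marker map from [makeMarkerMap()] (ordered within
#'   chromosomes).
#' @param qtl a [QTLModel-class]; all loci must sit at map markers.
#' @param seed integer seed (bit-identical families for identical seeds).
#' @param phenotypeName column name for the simulated phenotype.
#' @param missingRate fraction of genotype entries masked to NA.
#' @param pedigree family label.
#' @return a [BackcrossFamily-class].
#' @examples
#' map <- makeMarkerMap(nChrom = 2, markersPerChrom = 5)
#' qtl <- qtlModel(loci = data.frame(chrom = 1, pos = 50,
#'                                   origin = "hybrid", effect = 1))
#' fam <- genBackcross(50, map, qtl, seed = 1)
#' @export
genBackcross <- function(n, map, qtl = qtlModel(), seed = 1L,
                         phenotypeName = "trait", missingRate = 0,
                         pedigree = "BC_a") {
  if (n < 1) stop("n must be >= 1")
  if (any(unlist(tapply(map$pos, map$chrom, is.unsorted))))
    stop("marker map must be ordered within chromosomes")
  validObject(qtl)
  withSeed(seed, {
    chroms <- unique(map$chrom)
    simOne <- function() {
      do.call(cbind, lapply(chroms, function(ch)
        simulateGametes(n, map$pos[map$chrom == ch])))
    }
    gh <- simOne(); gp <- simOne()
    colnames(gh) <- colnames(gp) <- map$id
    rownames(gh) <- rownames(gp) <- sprintf("ind%d", seq_len(n))

    y <- rep(qtl@mean, n)
    if (nrow(qtl@loci)) for (i in seq_len(nrow(qtl@loci))) {
      loc <- qtl@loci[i, ]
      k <- markerIndexAt(map, loc$chrom, loc$pos)
      G <- if (loc$origin == "hybrid") gh else gp
      y <- y + loc$effect * G[, k]
    }
    if (nrow(qtl@epistasis)) for (i in seq_len(nrow(qtl@epistasis))) {
      ep <- qtl@epistasis[i, ]
      ki <- markerIndexAt(map, ep$chromI, ep$posI)
      kj <- markerIndexAt(map, ep$chromJ, ep$posJ)
      Gi <- if (ep$originI == "hybrid") gh else gp
      Gj <- if (ep$originJ == "hybrid") gh else gp
      hit <- Gi[, ki] == ep$genoI & Gj[, kj] == ep$genoJ
      y <- y + ep$effect * hit
    }
    if (qtl@residSd > 0) y <- y + rnorm(n, 0, qtl@residSd)

    if (missingRate > 0) {
      for (nm in c("gh", "gp")) {
        G <- get(nm)
        mask <- runif(length(G)) < missingRate
        G[mask] <- NA_integer_
        assign(nm, G)
      }
    }

    ph <- data.frame(id = rownames(gh), y, stringsAsFactors = FALSE)
    names(ph)[2] <- phenotypeName
    new("BackcrossFamily", markers = map, genoHybrid = gh, genoPure = gp,
        phenotypes = ph, pedigree = pedigree)
  })
}
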