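# QTL scans, thresholds, intervals, epistasis, extremes, F_ST.

mapStd <- makeMarkerMap(nChrom = 5, markersPerChrom = 10)
posAt <- function(k) mapStd$pos[k]

test_that("a constant phenotype scans to zero LOD with a flag", {
  fam <- genBackcross(50, mapStd, qtlModel(residSd = 1), seed = 1)
  fam@phenotypes$trait <- 1
  sc <- lodScan(fam, "trait")
  expect_true(all(scanTable(sc)$lod == 0))
  expect_true("constant_phenotype" %in% sc@flags)
})

test_that("degenerate perfect fits are capped and flagged", {
  fam <- genBackcross(60, mapStd, qtlModel(residSd = 1), seed = 2)
  fam@phenotypes$trait <- genotypes(fam, "hybrid")[, 13] + 0
  sc <- lodScan(fam, "trait")
  df <- scanTable(sc)
  expect_equal(df$lod[13], 300)
  expect_true("degenerate_fit_capped" %in% sc@flags)
  # markers on other chromosomes stay finite and uncapped
  expect_true(all(df$lod[df$chrom != 2] < 300))
})

test_that("the scan equals an exhaustive lm likelihood-ratio oracle", {
  q <- qtlModel(loci = data.frame(chrom = 3, pos = posAt(4),
                                  origin = "hybrid", effect = 0.8),
                residSd = 1)
  fam <- genBackcross(120, mapStd, q, seed = 3)
  sc <- scanTable(lodScan(fam, "trait", "hybrid"))
  X <- genotypes(fam, "hybrid") + 0
  y <- phenotypes(fam)$trait
  expect_lt(max(abs(sc$lod - lmLodOracle(X, y))), 1e-8)
})

test_that("observed LOD tracks the closed-form expectation", {
  # for a marker with squared correlation r2 to the phenotype,
  # E[LOD] ~ (n/2) log10(1 / (1 - r2))
  n <- 158; a <- 0.84; sdE <- 1        # ~15% variance explained
  r2 <- (a^2 / 4) / (a^2 / 4 + sdE^2)
  expected <- (n / 2) * log10(1 / (1 - r2))
  q <- qtlModel(loci = data.frame(chrom = 2, pos = posAt(5),
                                  origin = "hybrid", effect = a),
                residSd = sdE)
  lods <- vapply(1:50, function(s) {
    fam <- genBackcross(n, mapStd, q, seed = 300 + s)
    df <- scanTable(lodScan(fam, "trait", "hybrid"))
    df$lod[df$marker == "c2m5"]
  }, 0)
  expect_lt(abs(mean(lods) - expected), 2)
})

test_that("permutation thresholds follow quantile semantics and seeds", {
  fam <- genBackcross(80, mapStd, qtlModel(residSd = 1), seed = 5)
  t1 <- permutationThreshold(fam, "trait", "hybrid", nPerm = 150, seed = 9)
  t2 <- permutationThreshold(fam, "trait", "hybrid", nPerm = 150, seed = 9)
  expect_identical(as.numeric(t1), as.numeric(t2))
  # alpha = 1 gives the minimum of the permuted maxima
  tmin <- permutationThreshold(fam, "trait", "hybrid", nPerm = 150,
                               alpha = 1, seed = 9)
  expect_equal(as.numeric(tmin), min(attr(t1, "maxima")))
  expect_error(permutationThreshold(fam, "trait", nPerm = 50), "nPerm")
})

test_that("support intervals bracket the drop and extend one marker", {
  fam <- genBackcross(100, mapStd, qtlModel(residSd = 1), seed = 6)
  sc <- lodScan(fam, "trait")
  df <- scanTable(sc)
  # synthetic unimodal profile on chromosome 1
  sc@scan$lod <- ifelse(df$chrom == 1,
                        5 - abs(seq_len(nrow(df)) - 5) * 1.0, 0.1)
  iv <- lodInterval(sc, "c1m5", drop = 1.5)
  # markers 4..6 are within 1.5 of the peak; extension adds 3 and 7
  expect_equal(iv$loMarker, "c1m3")
  expect_equal(iv$hiMarker, "c1m7")
  # peak at a chromosome end gives a one-sided interval
  sc@scan$lod <- ifelse(df$chrom == 1,
                        5 - (seq_len(nrow(df)) - 1) * 1.0, 0.1)
  iv2 <- lodInterval(sc, "c1m1", drop = 1.5)
  expect_equal(iv2$loMarker, "c1m1")
  expect_equal(iv2$hiMarker, "c1m3")
})

test_that("variance explained matches its construction", {
  q <- qtlModel(loci = data.frame(chrom = 1, pos = posAt(3),
                                  origin = "hybrid", effect = 1),
                residSd = 0)
  fam <- genBackcross(100, mapStd, q, seed = 7)
  expect_equal(varianceExplained(fam, "trait", "c1m3", "hybrid"), 100)
  # independent of the marker at large n: near zero
  fam2 <- genBackcross(10000, mapStd, qtlModel(residSd = 1), seed = 8)
  expect_lt(varianceExplained(fam2, "trait", "c4m4", "hybrid"), 2)
  # planted 15%-variance QTL recovered within a few points on average
  pv <- vapply(1:20, function(s) {
    f <- genBackcross(158, mapStd,
                      qtlModel(loci = data.frame(chrom = 2, pos = posAt(5),
                                                 origin = "hybrid",
                                                 effect = 0.84),
                               residSd = 1), seed = 400 + s)
    varianceExplained(f, "trait", "c2m5", "hybrid")
  }, 0)
  expect_lt(abs(mean(pv) - 15), 4)
})

test_that("missing genotypes are imputed from flanking markers", {
  q <- qtlModel(loci = data.frame(chrom = 2, pos = posAt(5),
                                  origin = "hybrid", effect = 1),
                residSd = 0.5)
  famFull <- genBackcross(200, mapStd, q, seed = 9, missingRate = 0)
  famMiss <- genBackcross(200, mapStd, q, seed = 9, missingRate = 0.1)
  scF <- scanTable(lodScan(famFull, "trait", "hybrid"))
  scM <- scanTable(lodScan(famMiss, "trait", "hybrid"))
  # the peak survives imputation at nearly full strength
  expect_equal(scM$marker[which.max(scM$lod)],
               scF$marker[which.max(scF$lod)])
  expect_gt(max(scM$lod), 0.7 * max(scF$lod))
  # dropMissing reproduces the exclude-incomplete-markers behaviour
  scD <- scanTable(lodScan(famMiss, "trait", "hybrid", dropMissing = TRUE))
  expect_lt(nrow(scD), nrow(scM))
})

test_that("two-locus analysis separates epistatic from additive truths", {
  ep <- data.frame(chromI = 2, posI = posAt(5), originI = "hybrid",
                   chromJ = 4, posJ = posAt(5), originJ = "pure",
                   genoI = 1, genoJ = 1, effect = 1.5)
  fam <- genBackcross(158, mapStd, qtlModel(epistasis = ep, residSd = 1),
                      seed = 10)
  tl <- twoLocusAnalysis(fam, "trait", "c2m5", "c4m5", "hybrid", "pure")
  expect_equal(sum(tl@classes$n), 158L)
  # interaction contrast near its true value of 1.5
  expect_lt(abs(tl@contrast - 1.5), 3 * tl@contrastSE)
  # the shifted class alone carries a distinct letter
  l11 <- tl@classes$letter[tl@classes$genotype == "11"]
  others <- tl@classes$letter[tl@classes$genotype != "11"]
  expect_false(any(grepl(l11, others, fixed = TRUE)))
  # purely additive truth: large F, contrast within 3 SE of zero
  qa <- qtlModel(loci = data.frame(chrom = c(2, 4),
                                   pos = rep(posAt(5), 2),
                                   origin = c("hybrid", "pure"),
                                   effect = c(1, 1)), residSd = 1)
  famA <- genBackcross(5000, mapStd, qa, seed = 11)
  tlA <- twoLocusAnalysis(famA, "trait", "c2m5", "c4m5", "hybrid", "pure")
  expect_gt(tlA@fStat, 100)
  expect_lt(abs(tlA@contrast), 3 * tlA@contrastSE)
  # null truth at large n: all letters shared
  famN <- genBackcross(10000, mapStd, qtlModel(residSd = 1), seed = 12)
  tlN <- twoLocusAnalysis(famN, "trait", "c2m5", "c4m5", "hybrid", "pure")
  expect_true(length(unique(tlN@classes$letter)) == 1L)
})

test_that("extreme selection sizes and disjointness follow the fraction", {
  set.seed(13)
  v457 <- rnorm(457)
  sel <- selectExtremes(v457, sprintf("i%03d", 1:457), fraction = 0.035)
  expect_equal(sel$k, 16L)                  # ceiling(457 * 0.035)
  expect_equal(length(sel$low), 16L)
  expect_equal(length(sel$high), 16L)
  expect_length(intersect(sel$low, sel$high), 0)
  expect_equal(selectExtremes(rnorm(100), fraction = 0.035)$k, 4L)
  # boundary ties break by id
  vt <- c(0, 0, 0, 1, 2, 3)
  st <- selectExtremes(vt, 1:6, fraction = 0.34)  # k = ceiling(2.04) = 3
  expect_equal(sort(st$low), c(1, 2, 3))
  expect_error(selectExtremes(rnorm(3), fraction = 0.4), "overlap")
})

test_that("F_ST hits its boundary identities and the formula oracle", {
  map1 <- makeMarkerMap(nChrom = 1, markersPerChrom = 3)
  fam <- genBackcross(20, map1, qtlModel(residSd = 1), seed = 14)
  ids <- phenotypes(fam)$id
  # groups fixed for alternative alleles: F_ST = 1
  G <- genotypes(fam, "hybrid")
  G[1:10, ] <- 0L; G[11:20, ] <- 1L
  fam@genoHybrid <- G
  fs <- fstScan(fam, list(ids[1:10], ids[11:20]), nPerm = 0)
  expect_true(all(scanTable(fs)$fst == 1))
  # identical allele counts in both groups: F_ST <= 0
  G[1:10, ] <- rep(c(0L, 1L), each = 5)
  G[11:20, ] <- rep(c(0L, 1L), each = 5)
  fam@genoHybrid <- G
  fs0 <- fstScan(fam, list(ids[1:10], ids[11:20]), nPerm = 0)
  expect_true(all(scanTable(fs0)$fst <= 0))
  # monomorphic markers are reported missing
  G[] <- 0L
  fam@genoHybrid <- G
  fsM <- fstScan(fam, list(ids[1:10], ids[11:20]), nPerm = 0)
  expect_true(all(is.na(scanTable(fsM)$fst)))
  # random counts match the independently transcribed estimator
  set.seed(15)
  for (rep in 1:20) {
    n1 <- sample(4:30, 1); n2 <- sample(4:30, 1)
    a1 <- sample(0:n1, 1); a2 <- sample(0:n2, 1)
    g1 <- c(rep(1L, a1), rep(0L, n1 - a1))
    g2 <- c(rep(1L, a2), rep(0L, n2 - a2))
    theta <- danioscape:::wcTheta(mean(g1), n1, mean(g2), n2)
    expect_equal(theta, wcOracle(a1, n1, a2, n2))
  }
})

test_that("permutation P values flag a strongly differentiated marker", {
  q <- qtlModel(loci = data.frame(chrom = 3, pos = posAt(5),
                                  origin = "hybrid", effect = 2),
                residSd = 0.5)
  fam <- genBackcross(200, mapStd, q, seed = 16)
  ph <- phenotypes(fam)
  sel <- selectExtremes(ph$trait, ph$id, fraction = 0.08)
  # alpha chosen at the resolution 200 permutations can resolve after
  # Benjamini-Hochberg adjustment
  fs <- fstScan(fam, list(sel$low, sel$high), nPerm = 200, alpha = 0.05,
                seed = 17)
  df <- scanTable(fs)
  k <- which(df$marker == "c3m5")
  expect_equal(which.max(df$fst), k)
  expect_true(df$significant[k])
  # unlinked chromosomes are not flagged
  expect_false(any(df$significant[df$chrom == 5]))
})
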