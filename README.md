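# danioscape

Quantitative analysis of striped and spotted pigment patterns in
*Danio* fishes, and genetic mapping of pattern variation in
interspecific backcrosses.

Closely related *Danio* species display strikingly different adult
pigment patterns — horizontal stripes, spots, vertical bars, nearly
uniform fields — built from the same cell types: black melanophores,
orange xanthophores, and iridescent iridophores. Comparing such
patterns quantitatively, within and between species and across
development, requires (i) segmenting pigment cells from flank images,
(ii) reducing binarized patterns to comparable statistics, and
(iii) mapping the genetic architecture of pattern differences in
crosses. `danioscape` provides all three stages, plus seeded
synthetic-data generators so the entire pipeline is testable end to end
against known ground truth. It is aimed at researchers analysing fish
pigment-pattern images and backcross genotype data, and at
methodologists who need a fully reproducible reference pipeline.

## The statistics at the core

**Pattern morphospace.** A binarized pattern mask is reduced to the
standard deviation of its row-mean profile (dorsoventral, DV,
variation), the same over columns (anteroposterior, AP, variation),
and the ratio

&nbsp;&nbsp;&nbsp;&nbsp;log<sub>2</sub>(DV : AP) = log<sub>2</sub>( max(DV, 0.5) / max(AP, 0.5) )

Horizontal stripes sit at log<sub>2</sub> ≥ +2, vertical bars at ≤ −2,
uniform fields near 0, and spotted patterns in between with elevated
element counts. Element-level metrics (count, perimeter, area,
coverage) are exact integer computations on 8-connected components.

**Segmentation.** Melanophores are detected on the red channel after
local-median removal of bright glare, by Sauvola local thresholding

&nbsp;&nbsp;&nbsp;&nbsp;T(x,y) = m(x,y) · (1 + k·(s(x,y)/R − 1)),&nbsp;&nbsp; r = 25 px, k = 0.34, R = 128

followed by 8-connected components filtered to 100–1500 px²
(xanthophores: inverted red−blue difference, 10–200 px²).

**Genetics.** Single-QTL genome scans by Haley–Knott regression,
LOD = (n/2)·log₁₀(RSS₀/RSS₁), with genome-wide permutation
thresholds, 1.5-LOD support intervals, per-marker percent variance
explained, two-locus epistasis analysis (ANOVA + interaction contrast +
Tukey compact letter display), and extreme-phenotype
F<sub>ST</sub> scans using the Weir–Cockerham estimator on the 0/1
allele codes of each transmitting parent.

## Worked example

Generate a spotted flank image with known ground truth, segment it, and
place it in the morphospace:

```r
library(danioscape)

spec <- patternSpec("spots", nElements = 12L, elementWidth = 90, seed = 7)
out  <- genPatternImage(spec)
seg  <- segmentMelanophores(out$image)
seg$cells
#> CellSet: 135 cells (135 melanophores, 0 xanthophores), 1 frame(s)

mask <- buildElementMask(seg$cells, dim(out$image)[1:2])
round(patternStats(mask, seg$cells), 3)
#>       dv     ap log2Ratio elementCount elementPerimeter elementArea coverage
#> 1 87.041 54.892     0.665           12             5940      107124    0.409
```

All 135 planted melanophores were recovered; the twelve spots produce a
log₂(DV:AP) of 0.67 — intermediate between stripes (≥ +2) and bars
(≤ −2), with the elevated element count typical of spotted patterns —
and melanized elements cover 41% of the flank.

Simulate a backcross family segregating a nearest-neighbour-distance
QTL and map it:

```r
map <- makeMarkerMap()                      # 25 chromosomes x 10 markers
qtl <- qtlModel(loci = data.frame(chrom = 15, pos = map$pos[5],
                                  origin = "hybrid", effect = 0.9),
                residSd = 1)
fam <- genBackcross(158, map, qtl, seed = 7, phenotypeName = "nnDist")

scan <- lodScan(fam, "nnDist", origin = "hybrid")
thr  <- permutationThreshold(fam, "nnDist", origin = "hybrid",
                             nPerm = 1000, seed = 8)
scan <- findPeaks(scan, thr)
scan
#> QTLScanResult: 'nnDist' on the hybrid-parent transmission, 250 markers, n = 158
#>   max LOD 6.14 at c15m5; threshold 3.00 (alpha = 0.05)
#>   1 peak(s) above threshold
peaks(scan)
#>   marker chrom      pos      lod       lo       hi loMarker hiMarker   pctvar
#> 1  c15m5    15 44.44444 6.136186 33.33333 55.55556    c15m4    c15m6 16.37681
```

The planted locus is recovered at LOD 6.1 (threshold 3.0), with a
1.5-LOD support interval spanning 33–56 cM on the planted chromosome
and 16% of phenotypic variance explained — close to the 15% the
simulated effect size implies. `plotScan(scan)` draws the genome scan.

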