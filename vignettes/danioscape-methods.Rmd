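---
title: "Quantifying striped and spotted pigment patterns: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying striped and spotted pigment patterns: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(danioscape)
```

# Overview

`danioscape` implements a pipeline for comparing striped and spotted
pigment patterns in *Danio* fishes at three levels: whole-pattern
morphospace statistics computed from binarized flank images, cell-level
metrics (counts, spacing, pigment areas, movement) computed from
segmented melanophores and xanthophores, and genetic mapping of pattern
variation in interspecific backcross families. Because real flank images
and genotype matrices of this kind are not generally available at desk
scale, the package ships seeded generators that produce ground-truthed
synthetic versions of every input, and the test suite exercises each
stage against that ground truth. This vignette explains the models and
procedures, the tunable parameters and their defaults, the numerical
choices, and what the synthetic data do and do not establish about
behaviour on real images.

# Segmentation

## The operator chain

Melanophores are detected from an RGB region of interest (ROI) by a
fixed operator chain:

1. **Bright-outlier removal.** Specular glare from iridophores appears
   as small, near-white patches. Every pixel brighter than its local
   median (square window of side $2r+1$, $r = 25$ px) by more than
   $t = 50$ grey units is replaced by that median. The window radius
   follows the 25 px convention used throughout; the excess threshold
   $t$ is a package choice: large enough that legitimate bright tissue
   (background, xanthophores) is untouched, small enough that saturated
   glare ($\ge 245$) on any realistic background is removed. The
   operator is idempotent on glare-free images and leaves constant
   images unchanged.
2. **Red channel isolation.** Melanin is dark in all channels, but the
   red channel best separates black melanophores from orange
   xanthophores (high red) and the pinkish skin background.
3. **Sauvola local thresholding.** The per-pixel threshold is
   $$T(x,y) = m(x,y)\left(1 + k\left(\frac{s(x,y)}{R} - 1\right)\right)$$
   with $m$ and $s$ the mean and standard deviation of the local window
   (radius 25 px, square, replicate-padded), $k = 0.34$, and dynamic
   range $R = 128$. A pixel strictly below its threshold is foreground.
   The method was designed for many small dark objects on a light
   field — printed text originally, contracted melanophores here. On a
   constant image $s = 0$ gives $T = 0.66\,m < m$, so the mask is
   empty: a blank flank yields no cells, by construction rather than by
   special-casing.
4. **Connected components and size band.** 8-connected components with
   area 100–1500 px$^2$ are retained as melanophores; centroids are
   unweighted means of component pixel coordinates, 0-based, x =
   column, y = row.

Xanthophores use the same machinery on a derived grey image: the
clipped channel difference $\max(\mathrm{red}-\mathrm{blue},0)$ is
bright over orange cells (high red, low blue) and near zero elsewhere,
so its inversion makes xanthophores dark objects for the identical
Sauvola detector; components of 10–200 px$^2$ are retained. Manual
corrections are consumed as an edit list: removed ids are dropped and
each added point becomes a circle of diameter 15 px (area
$\mathrm{round}(\pi \cdot 7.5^2) = 177$ px$^2$), so corrected and
detected cells are commensurate.

## Numerical choices

The local window is square (side $2r+1$) rather than circular: a square
window admits an exact integral-image implementation, which makes the
operator both fast and *oracle-verifiable* — the test suite asserts
pixel-for-pixel equality with a brute-force double loop over windows.
Whether the original tooling used a square or circular window, and its
exact $R$, are not documented; both the window shape convention and $R$
are exposed as arguments. Borders are replicate-padded, which avoids
spurious border detections and keeps the operator deterministic. The
window standard deviation uses the population ($n$) denominator, the
convention under which the constant-image identity above is exact.

# Pattern morphospace

## Element masks

Whole melanized elements (entire stripes or spots) are reconstructed
from individual cells as the union of disks of radius 20 px about each
melanophore centre — 20 px approximates the average nearest-neighbour
distance between melanophores, so disks of adjacent cells merge into
whole elements. Disks are exact Euclidean lattice disks (the r = 20
disk contains 1257 integer pixel centres), not morphological brushes,
so element areas are reproducible integers. An `expand_blur` variant
Gaussian-blurs the dilated mask ($\sigma = 5$ px, a package default;
the blur parameters of the original processing chain are not
documented) and rethresholds at 50% intensity, bridging small gaps the
way overlapping natural cell edges do. For published images that cannot
be segmented cell-wise, `binarizeByFraction()` chooses the global
threshold whose foreground fraction is nearest a target (ties toward
the lower threshold), mimicking manual thresholding to a comparable
amount of segmented pixels.

## DV/AP variation and the log-ratio

The morphospace coordinates of a binarized pattern are:

- **DV variation** — the standard deviation, across rows, of the
  row-mean grey profile (each row is one anteroposterior transect);
- **AP variation** — the same computation over columns;
- **log$_2$(DV:AP)** — $\log_2$ of the ratio after flooring both terms
  at 0.5 grey units.

Patterns uniform along an axis approach 0 on that axis; horizontal
stripes therefore sit at high DV / low AP (log-ratio $\ge +2$ in
practice), vertical bars mirror them ($\le -2$), spotted patterns are
intermediate with elevated element counts, and uniform fields sit near
0. The floor prevents a near-empty or fully covered mask — where both
variations are numerically tiny — from producing an explosive or
undefined ratio; both-zero inputs map to exactly 0. The standard
deviation uses the sample ($n-1$) denominator by default, matching
common spreadsheet/ImageJ behaviour; a population-SD switch is provided
since the original convention is not documented. Profiles are computed
on the 0/255 mask directly, with no anti-aliasing, because the
upstream definition operates on binary images.

Element-level metrics are exact integer computations: count of
8-connected components, total perimeter as the number of 4-connected
foreground/background pixel edges (image border included) — chosen over
Crofton-style estimators precisely because it is exact and
oracle-friendly — total area, and coverage (foreground fraction of the
ROI).

## The stripes-to-spots transformation

Ontogenetically, spotted species first build stripes that later break
into spots. `splitStripesToSpots()` reproduces this signature on masks:
each stripe component is replaced by aligned blocks whose pixel areas
sum *exactly* to the stripe's area, centred on the stripe's row band
and expanded vertically up to twofold — but never past the midline gap
to a neighbouring stripe, so chains from different stripes cannot
merge. The transformation conserves melanized area while strictly
raising AP variation and element count and strictly lowering the
log-ratio, which is the property the test suite asserts over seeded
stripe masks.

# Cell-level metrics and tracking

Nearest-neighbour distances are computed exactly from all pairwise
distances (ties broken toward the lower cell id); medians of
nearest-neighbour distance and pigment area are reported per
individual, the former only when ten or more cells of the class are
present. Density is count per ROI area. When aggregating across
individuals the package takes medians of per-individual medians, so
each fish contributes one value regardless of its cell count.

Daily image series are registered to the first frame by composing
pairwise rigid transforms. Each pairwise transform is estimated
robustly from unlabeled point sets: a random ordered pair of points
from one day is matched against every distance-compatible ordered pair
from the previous day; each candidate hypothesis is prefiltered by
projecting a third probe point, survivors are scored by inlier count
(residual < 3 px) with ties broken by inlier residual, and the winner
is refined by least-squares (Kabsch) refits until the inlier matching
stabilizes. Registration *fails with a flag* — never silently — when no
hypothesis reaches the required inlier fraction (default 0.20).

Linking uses greedy nearest-pair assignment under a 100 px/day
displacement cap, with one missing day bridged at twice the cap (the
gap-closing distance of the original protocol is not documented; twice
the per-day cap is the natural extrapolation). Greedy assignment is
deterministic and, on well-separated cells, identical to the optimal
assignment; an exact minimum-cost bipartite variant (an $O(n^3)$
Hungarian solver) is available behind `method = "optimal"`, and the
test suite checks small-$n$ agreement between the two. Motion
statistics cover tracks spanning at least 7 days with at most one
missing day: net start-to-end displacement and median per-interval
speed.

# Backcross genetics

## The cross design and genotype codes

An F1 hybrid crossed back to one parental species yields individuals
carrying, per chromosome, one recombinant haplotype from the hybrid
parent and one from the pure-species parent. Both transmissions are
informative: the hybrid parent's 0/1 code tracks alleles *differing
between species*, while the pure parent's 0/1 code (which of that
parent's two haplotypes was transmitted) tracks variation *segregating
within* the pure species. The package therefore stores two genotype
matrices per family and scans them separately by origin, mirroring the
two-colour scan traces of the study design this emulates.

## Haley–Knott scans, thresholds, intervals

At each marker the phenotype is regressed on the genotype probability:
the observed 0/1 code where genotyped, and where missing the
conditional expectation given the nearest flanking genotyped markers
under the Haldane mapping function — this imputation is what makes the
regression Haley–Knott rather than simple marker regression. The LOD
score is $\frac{n}{2}\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$;
degenerate perfect fits are capped at 300 and flagged, and a constant
phenotype scans to all-zero with a flag. Markers with missing genotypes
are *retained* (imputed) by default; a `dropMissing` flag reproduces
the stricter exclude-incomplete-markers behaviour.

Genome-wide significance uses permutation: phenotype labels are
shuffled, the genome-wide maximum LOD recorded per permutation, and the
threshold taken as the empirical $1-\alpha$ quantile (type-7
interpolation). The upstream description labels such thresholds "false
discovery" thresholds while using permutation machinery; the package
implements the genome-wide permutation quantile as the default reading
and offers marker-wise Benjamini–Hochberg adjustment (in the F$_{ST}$
scan) as the alternative — both readings are defensible, so both are
exposed. Support intervals take the contiguous run of markers within
1.5 LOD of the peak, extended one marker beyond on each side where
available: a deliberately conservative convention whose simulated
coverage of the true locus exceeds 90%. Variance explained is
$100\,(1-\mathrm{RSS}_1/\mathrm{RSS}_0)$ from the single-marker fit.

## Epistasis

Two-locus analysis compares the four genotype combinations by one-way
ANOVA plus the $2\times2$ interaction contrast
$\bar y_{11}-\bar y_{10}-\bar y_{01}+\bar y_{00}$ (zero under
additivity; its standard error comes from the pooled residual mean
square). All-pairs Tukey studentized-range comparisons are summarized
as compact letter displays; letters are derived as maximal cliques of
the not-significantly-different graph, which is the exact CLD
semantics. A natural-log transform is available for count phenotypes
whose residual variance grows with the mean. The generative model used
in tests shifts *only* the double stripe-allele class, and the suite
asserts that this class alone receives a unique letter in at least 80%
of simulated families of 158.

## Extreme-phenotype F$_{ST}$ scans

For large sibships, genotyping only the phenotypic tails concentrates
information about major-effect loci. `selectExtremes()` takes the
$\lceil 0.035\,n\rceil$ lowest and highest individuals (16 per tail at
$n = 457$; the fraction is applied literally even though the study
design this follows quotes 18 per tail from the same arithmetic — the
selection follows the stated fraction and documents the discrepancy
rather than guessing at an unstated rounding rule). Per-marker
differentiation between tails uses the Weir–Cockerham (1984)
variance-components estimator applied to the 0/1 allele codes (one
transmitted allele per individual):
$$\hat\theta = \frac{\mathrm{MSP}-\mathrm{MSG}}
  {\mathrm{MSP}+(n_c-1)\,\mathrm{MSG}}$$
with MSP and MSG the among- and within-group mean squares and $n_c$
the variance-effective group size. The estimator can be slightly
negative under no differentiation and is *not* clamped (a clamp would
bias means); monomorphic markers are reported as missing rather than
zero. The exact estimator used by the original genotyping pipeline is
unspecified; Weir–Cockerham is the field-standard default here and the
estimator seam is a single internal function. Per-marker significance
uses label permutations with Benjamini–Hochberg adjustment across
markers — note that $B$ permutations cannot produce adjusted $P$ values
below roughly $(1/(B+1))\cdot(\textrm{markers}/\textrm{ties})$, so the
significance level must be chosen commensurate with $B$.

# The synthetic-data generators

## What they emulate

`genPatternImage()` renders the cellular anatomy the segmentation
assumes: dark melanophore disks (nominal radius 8 px, Gaussian-perturbed,
area $\approx 200$ px$^2$) tiling the dark elements of a layout on a
jittered hexagonal lattice at 26 px spacing; small orange xanthophore
disks (radius 4 px, $\approx 50$ px$^2$) tiling the light regions; a
light-pink background (RGB 190, 165, 170) standing in for skin and
muscle; and saturated near-white glare disks of radius 1–3 px at a
chosen pixel density, emulating iridophore reflections. Layouts are
horizontal stripes, vertical bars, spot grids, uniform fields, and
blank backgrounds. The uniform layout — a diffuse, fully melanized
flank such as the nearly uniform patterns seen in some species — uses a
slightly denser square grid whose element disks tile the whole ROI, so
its mask genuinely carries no axis structure. The ROI defaults to
512×512 px with all distances in pixels, matching the convention of
working in pixels after isometric scaling.

`genDevelopmentSeries()` adds time: persistent cell identities, new
cells appearing unpaired at a Poisson rate (de novo differentiation,
not division), optional per-day loss, and two motion regimes. In
`spot_consolidate`, each cell receives a personal target — the nearest
spot attractor plus the cell's own offset shrunk by a consolidation
factor (default 0.35) — and moves toward it by exactly
$\min(\mathrm{drift}, \mathrm{distance})$ px/day, so cells pack into
spots without collapsing onto a point; `stripe_hold` wiggles cells by
at most $0.2\,\mathrm{drift}$. True per-day displacement vectors are
recorded. No quantitative appearance or loss rates are documented for
adult melanophores, so the defaults (2 cells/day appearing, no loss)
are free parameters chosen to look like the daily series they emulate,
not calibrated to any published curve.

`genBackcross()` simulates gametes marker-by-marker along each
chromosome with switch probabilities from the Haldane (no-interference)
mapping function — the simplest standard model, and one with a
closed-form oracle ($r = (1-e^{-2d/100})/2$ at $d$ cM) that the tests
check directly. The two transmitting parents are simulated
independently; the pure parent is coded as two haplotypes so that
intraspecific variation is simulable. Phenotypes are
$\mu + \sum_l a_l g_l + \sum_{ij} \gamma_{ij}\,
[\,g_i, g_j \text{ at the stated combination}\,] + N(0,\sigma)$.
The default map (25 chromosomes × 10 markers, 100 cM each) matches the
karyotype scale of the system; simulated family sizes in the tests
(158 and 457 with 3.5% tails) match the two cross designs this
pipeline addresses.

## What passing tests do not show

The generators produce epinephrine-contracted, well-separated,
circular cells under even illumination on pre-aligned ROIs. Passing
the recovery suites therefore demonstrates that the operator chain and
its parameters are implemented correctly and are internally consistent
— not that segmentation accuracy transfers to uncontracted cells,
overlapping cells, uneven lighting, compression artifacts, or
imperfect ROI alignment, all of which the original protocol handled
with manual correction. Similarly, the Haldane simulator has no
crossover interference and no genotyping error beyond random
missingness, so mapping power estimates are upper bounds for real
RAD-seq data.

# Problem sizes and reproducibility

The test suite and the acceptance script run everything at fixed,
modest scales chosen to keep a full run in minutes on one core while
leaving the statistical assertions comfortably powered: 20 seeded
images per layout for the morphospace suite; 5 glare-bearing images
for segmentation recovery; 200 null families × 200 permutations for
type-I calibration (the canonical 1000-permutation threshold is used
in analyses; 200 suffice to calibrate the 5% quantile in aggregate);
100 simulated families of 158 for power, interval coverage, epistasis
letter recovery, and cross-origin separation; and 100 families of 457
for the extreme-tail F$_{ST}$ scan. `scripts/acceptance.R` recomputes
the same quantities from scratch at half scale under a user-supplied
seed and writes them as JSON.

Every stochastic routine takes an explicit seed and restores the
caller's RNG state, so identical seeds give bit-identical images,
series, and families, and a fixed-seed run of the suite is fully
deterministic.

# Known limitations

- Iridophores are modelled only as glare to be removed; they are not
  segmented (individual iridophores are not reliably distinguishable
  in brightfield), and erythrophores and aged-fish stripe reticulations
  are out of scope.
- The morphospace collapses visually distinct patterns that share axis
  statistics (a known property of the two-axis design); element counts
  partially disambiguate them.
- Greedy linking can mislabel cells that pass within the inter-cell
  distance of each other; the optimal-assignment variant reduces but
  cannot eliminate this, since the ambiguity is in the data.
- The LOD scan is single-QTL; no multi-QTL model search or composite
  interval mapping is attempted.
- F$_{ST}$ permutation $P$ values are resolution-limited by the
  permutation count, as noted above.
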