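---
title: "Methods: linking genetic structure to winter space use"
author: "winterlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking genetic structure to winter space use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(winterlink)
```

winterlink implements the computational chain used to ask whether colonial
seabird populations that share wintering areas are also genetically more
similar: microsatellite F-statistics on the genetic side, light-level
geolocation and kernel utilization distributions on the movement side, and
a randomization test tying the two pairwise matrices together. This
vignette is the package's account of the models, the parameters that
matter, the numerical conventions, and what the tests do and do not show.

## Genetic differentiation

**Estimator.** `amovaFst()` is an allele-level AMOVA with among- and
within-population components only. Per locus, gene copies (two per
non-missing genotype; missing genotypes dropped per locus) contribute sums
of squares partitioned among and within populations; variance components
are summed across loci before forming
$F_{ST} = \sigma^2_{AP}/(\sigma^2_{AP} + \sigma^2_{WP})$. A negative
summed among-population component is truncated to zero *for reporting*;
the permutation test compares untruncated estimates, because truncation
piles ties at zero and distorts the null (a choice visible in the
calibration test: permutation p-values on exchangeable data are
approximately uniform).

**Standardization.** Microsatellites are highly polymorphic, which caps
attainable $F_{ST}$ well below 1. `maxFstRecode()` relabels every allele
so that populations share none while each within-population frequency
spectrum is untouched; $F'_{ST}$ is the observed $F_{ST}$ divided by the
recoded (maximal) one. Fixed-different populations give exactly 1;
relabeling alleles globally changes nothing.

**Significance.** Pairwise permutation tests shuffle individuals between
the two colonies (sizes preserved), with the add-one estimator
$p = (1 + \#\{F^{perm} \ge F^{obs}\})/(1 + n_{perm})$, default 999
permutations. Multiple testing uses the modified FDR threshold
$\alpha / \sum_{i=1}^k 1/i$ (`narumFdr()`), the convention in this
literature for large batteries of pairwise tests.

**Hardy–Weinberg.** `hweExactMC()` runs a Guo–Thompson-style chain:
repeatedly pick two individuals and swap one randomly chosen allele
between them. A point worth recording: on the *labeled-individual* state
space the stationary distribution under random union of gametes is
proportional to $2^H$ (H the heterozygote count), and the proposal's
heterozygote asymmetry (a heterozygote offers two distinguishable
alleles, a homozygote one) cancels it exactly — every swap is accepted.
The genotype-count table is maintained only to score each visited state
by Levene's conditional probability; the p-value is the fraction of
states no more probable than the observed one, estimated per batch
(defaults 2000 dememorization steps, 300 batches of 1000) with the
between-batch standard error. The chain was validated against full
enumeration (`hweExactBiallelic()`) and against a direct random-pairing
simulation during development; the enumeration check is kept in the test
suite.

**Rarefied allelic richness.** The closed form
$\sum_i [1 - \binom{N-N_i}{g}/\binom{N}{g}]$ over alleles, computed with
log-binomials. The published standardization "to a sample size of 10" is
ambiguous between 10 diploid individuals (20 gene copies) and 10 copies;
the default is `gCopies = 20` (gene counting, as HP-Rare does) and the
alternative is one argument away. Neither reading is asserted against the
published per-colony values, because the raw genotypes are not deposited.

**PCoA.** `pcoa()` double-centers the pairwise matrix and
eigendecomposes, reporting percent variation over positive eigenvalues.
The consequential convention: GenAlEx-style $F'_{ST}$ matrices are
treated as *squared* distances, i.e. the centered matrix is $-d/2$, not
$-d^2/2$ (`assumeSquared = TRUE`, the default). This is the variant that
reproduces all three published axis decompositions from the transcribed
pairwise table — 55.7/17.5/8.4% (all 17 colonies), 77.5/15.4/6.8% (the
five western colonies), 47.3/16.5/13.2% (the twelve eastern colonies) —
to the printed precision; the $-d^2/2$ variant does not (66.2% on axis
1 for the 17-colony matrix) and remains available by argument. The
acceptance script recomputes the first two of these.

## Light-level geolocation

`fitTrack()` is a threshold-free hidden Markov model: hidden states are
the ocean cells of a lon/lat grid, the day's observation is its full
binarized light/dark pattern, and decoding is exact Viterbi.

- **Emission.** At a sample time, light is expected when the sun's
  elevation at the cell exceeds $90 - \text{zenith}$. A daylight sample
  reads dark with shading probability $q = 1/(1+\alpha)$ (default
  $\alpha = 5$, $q \approx 0.17$, moderate shading); a night sample reads
  light with probability $10^{-6}$. The named $\alpha$ parameter is given
  this functional role as a local convention; reproducing the exact
  shading likelihood of the originating geolocation package is explicitly
  not claimed, and the same caveat applies to the movement prior.
- **Movement.** Transitions are Gaussian in cell distance with daily
  scale $\beta$ cells (default 5), truncated at $3\beta$ and renormalized
  over ocean cells, so rows sum to one and land is unreachable.
- **Solar ephemeris.** The NOAA polynomial algorithm, geometric elevation
  (no refraction — the calibrated zenith absorbs it); the test suite
  checks ten random space-time points against an independently coded
  Astronomical Almanac formula at 0.3°.
- **Calibration.** From the pre-deployment groundtruth days:
  the threshold is the maximum lux seen in astronomical night plus a
  margin; the zenith maps observed dawn/dusk transition midpoints (the
  first and last light samples of a day bounded by a dark neighbour —
  interior flips are shading, not twilight) to solar elevations at the
  known site.
- **Days.** Segments are cut at the local midnight of a configurable
  meridian (default 180°) so the study window's daylight period is never
  split, and each segment is labelled with the UTC date its daylight
  falls on (for west-of-dateline longitudes, the boundary date minus
  one). A day missing more than one hour of samples, or with no light
  variation at all (polar night), is flagged missing and bridged by the
  movement model without an emission term.
- **Two passes.** `twoPassFit()` first fits a 4° version of the grid and
  excludes days flagged missing, days whose best per-sample emission
  log-likelihood falls strictly below the record's 1st percentile, and
  days more than 1 nat per sample below the record median (patterns no
  cell can reconcile, e.g. light in the middle of the night — the
  absolute guard is needed because a percentile alone can neither flag
  several corrupt days nor stay silent on clean records); the 1° refit
  excludes those days.

Simulation scale: recovery tests run on a 25°×20° coastal sub-grid
(~250–500 ocean cells, 25–46 days, 10-minute sampling), where a
stationary noiseless bird is recovered with every day within one cell and
a moving, 15%-shaded track with median error under two cells. Dates stay
inside mid-November–early-February, away from the equinoxes where
light-level latitudes degrade. Viterbi exactness is checked against full
path enumeration on a masked 5×5-cell, 6-day toy (12 ocean cells,
$12^6$ paths).

## Space use

`kernelUD()` evaluates an isotropic bivariate normal kernel (bandwidth in
degrees, the ad hoc rule
$h = \tfrac12(sd_{lon}+sd_{lat})\,n^{-1/6}$) at the 1° cell centers and
normalizes to unit mass. KDE in degrees matches the study's grid
definition; areas are computed per cell on the sphere
($(111.195\ \mathrm{km} \cdot cs)^2 \cos\varphi$), a stated approximation
at 37–60°N. Isopleths (`udIsopleth()`) take the smallest set of
highest-mass cells reaching the level, ties broken by the grid's linear
cell index for bit-reproducibility; polygons are traced on cell
boundaries and projected to a Lambert azimuthal equal-area plane centered
on the mean of the selected cell centers (the study does not state its
projection center).

`udoi()` implements
$UDOI = A_{overlap} \sum_{cells} (m_a/A_c)(m_b/A_c)A_c$ over the cells
where both surfaces are positive: 1 for identical uniform ranges, 0 for
disjoint ones, above 1 for concentrated ranges sharing their high-use
areas. Whether the published values restricted the computation to a 95%
isopleth is unstated; the default uses the full shared support and
`restrictLevel` selects the restricted variant. Grid refinement
(2°→1°→0.5°) converges to an independent fine-grid integration within 1%
on Gaussian test surfaces.

Duplication of identical tracks leaves a colony aggregate unchanged at
fixed bandwidth; the default ad hoc bandwidth depends on pooled sample
size, which is why the corresponding test pins `h`.

## The association tests

`associationTests()` computes Spearman's r (Pearson correlation of
mid-ranks) between pairwise $F'_{ST}$ and (i) great-circle distance
between colonies (haversine, R = 6371 km) with alternative *greater*
(isolation by distance) and (ii) the UDOI overlap with alternative *less*
(shared winters, less differentiation). Significance comes from the
study's stated scheme — hold the $F'_{ST}$ values fixed and randomly
re-assign the partner values to pairs, 5000 times — which permutes the
pair matching rather than matrix rows and columns; a full Mantel
row/column permutation is deliberately out of scope. One-tailed p-values
in the direction of each stated hypothesis, with the add-one correction;
decisions at $\alpha = 0.10$.

**Colony set.** The overlap test runs over the 11 colonies present in
both the genetic and the overlap tables (55 pairs). For the distance test
the package defaults to the *same* 55 pairs: on the transcribed tables
this reproduces the published correlation (r = 0.095 vs printed 0.08,
randomization p ≈ 0.25 vs printed 0.290), whereas the 12-colony/66-pair
set (all eastern colonies with genetic data) gives r = 0.004 — the
shared-pair reading is evidently what the published test used, and the
66-pair variant stays available through `ibdLabels`. The distance metric
behind the printed value is not stated (coastline distance is plausible);
great-circle is the default and the rank-based correlation limits the
sensitivity of that choice. On the same tables the overlap correlation
computes to r = −0.209 against the printed −0.22, within rounding and
transcription precision of a 2-decimal table.

## Synthetic data

The generators exist so every pipeline stage can be exercised, and its
estimators validated, without the undeposited field data.

- `simulateGenotypes()`: Balding–Nichols island model — per population
  and locus, allele frequencies drawn from a Dirichlet with mean equal to
  the ancestral frequencies and concentration $(1-F)/F$, so F is a known
  recovery target. Defaults mirror the study design: 18 colonies with the
  published sample sizes (7–53, 424 individuals), 10 loci, within-region
  F = 0.04, and a deep east–west split created by giving the five
  "western" populations an independent ancestral spectrum. What it does
  *not* emulate: stepwise mutation, null alleles, scoring error,
  linkage — so passing recovery tests validate the estimators, not the
  robustness of the pipeline to those artefacts.
- `simulateTrack()` / `simulateLight()`: a biased random walk on ocean
  cells, and its light record as the exact inverse of the emission model
  (bright iff the sun is up at the true position and the sensor is
  unshaded), with a ≥3-day groundtruth segment prepended. Real light
  records carry weather, sensor response curves and behaviour-driven
  shading that the simulator does not attempt.
- `syntheticSeaMask()`: a procedural coastline (half-plane plus smooth
  sinusoids) so no geographic download is needed; a real mask can be
  supplied as a `GridSpec`.
- `loadStudyTables()`: transcriptions of the published colony,
  differentiation, home-range and overlap tables, checksum-locked in the
  test suite; colony-name aliases ("Farallones"/"Southeast Farallon")
  resolve through the colony table.

All generators are seed-deterministic: identical configuration and seed
give identical bytes.

## Numerical conventions and degenerate inputs

- Half-missing genotype calls are coerced to fully missing on read (the
  GenAlEx convention); allele labels are kept as integer repeat sizes.
- Permutation and randomization p-values use add-one estimators and are
  bit-reproducible given a seed.
- Isopleth ties: linear cell index, latitude varying fastest.
- Degenerate cases are errors, not silent results: empty populations,
  all-dark calibration records, fewer than five kernel points, zero rank
  variance in the correlation, matrices with NA after symmetrization.
- A monomorphic locus returns HWE p = 1 with a degenerate flag.

## Known limitations

- The shading and movement parameterizations are self-consistent
  stand-ins for the originating geolocation package's unpublished ones;
  absolute track accuracy against real tags is untested here.
- KDE in geographic degrees distorts east–west distances at high
  latitude; within the study band the effect is modest but real.
- Published per-colony diversity values (and the global $F_{ST}$ = 0.039)
  are not recomputable without the raw genotypes; they enter only as
  transcription fixtures, and the pipeline's numerical claims are
  restricted to what the printed tables support.
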