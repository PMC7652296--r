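# winterlink

Does segregation in wintering areas go hand in hand with population
genetic structure? For colonial seabirds such as the rhinoceros auklet
(*Cerorhinca monocerata*), breeding colonies are discrete and philopatry
restricts gene flow, but the non-breeding season — when birds from many
colonies could mix at sea — is the hypothesized link between movement and
structure. winterlink implements the full analysis chain needed to test
that hypothesis:

- **Population genetics of microsatellites**: AMOVA-framework F_ST and the
  standardized F′_ST (F_ST divided by its maximum given within-population
  diversity, obtained by recoding alleles to be population-unique),
  permutation significance, modified-FDR correction
  (α / Σ 1/i), Nei heterozygosities, private alleles, rarefied allelic
  richness Σᵢ[1 − C(N−Nᵢ, g)/C(N, g)], a Guo–Thompson Markov-chain exact
  test of Hardy–Weinberg proportions, and PCoA of pairwise matrices.
- **Light-level geolocation**: a threshold-free hidden Markov model whose
  hidden states are ocean grid cells and whose observation is each day's
  full light/dark pattern (zenith 96°, threshold 10 lux, shading
  probability 1/(1+α), Gaussian movement kernel of scale β cells/day),
  decoded exactly by Viterbi in two passes (4° screening, 1° refit).
- **Space use**: kernel utilization distributions on the 1° grid with the
  ad hoc bandwidth ½(sd_lon+sd_lat)·n^(−1/6), 50/90% home-range isopleths
  with spherical areas in km², and the UDOI overlap index
  A_overlap·ΣUD_a·UD_b (1 = identical uniform ranges, 0 = disjoint, >1 =
  shared concentration).
- **The headline statistic**: Spearman correlation between pairwise F′_ST
  and (i) great-circle distance between colonies (isolation by distance)
  and (ii) winter overlap, with a Mantel-style randomization p-value that
  re-assigns partner values to pairs 5000 times.

Because the underlying field data are not public, the package ships
seed-deterministic simulators (Balding–Nichols genotypes with known F,
ocean random-walk tracks, synthetic light records, a procedural sea mask)
plus transcriptions of the published summary tables, so every stage runs
and is validated end to end.

## Worked example

Correlating genetic differentiation with winter overlap on the packaged
study tables:

```r
library(winterlink)
tabs <- loadStudyTables()
res <- associationTests(tabs$fstPrime, tabs$udoi, tabs$colonies,
                        nPerm = 5000, seed = 1)
res$overlap
#> AssociationResult: Spearman r = -0.209 over 55 pairs, p = 0.0708 (less, 5000 randomizations, seed 2)
res$ibd
#> AssociationResult: Spearman r = 0.095 over 55 pairs, p = 0.2484 (greater, 5000 randomizations, seed 1)
```

Colonies that overlap more in winter are less differentiated (negative r,
suggestive at the study's α = 0.10), while distance alone explains
nothing — the isolation-by-distance correlation is weak and
non-significant. The PCoA of the same F′_ST matrix separates the western
from the eastern Pacific colonies on its first axis:

```r
pc <- pcoa(tabs$fstPrime)
round(pc$percent[1:3], 1)
#> [1] 55.7 17.6  8.4
```

On synthetic data the chain runs without any fixture: simulate an
east–west split, estimate differentiation, and watch F′_ST pick up the
block structure:

```r
sim <- simulateGenotypes(nPops = 4, nPerPop = 30, nLoci = 8, F = 0.05,
                         nWest = 2, missingRate = 0, seed = 42)
pd <- pairwiseDifferentiation(sim$genotypes, nPerm = 199, seed = 1)
round(as.matrix(pd$fstPrime), 3)
#>       pop01 pop02 pop03 pop04
#> pop01    NA 0.293 0.542 0.715
#> pop02 0.293    NA 0.565 0.679
#> pop03 0.542 0.565    NA 0.189
#> pop04 0.715 0.679 0.189    NA
```

Cross-block pairs (pop01/pop02 vs pop03/pop04) are several times more
differentiated than within-block pairs, as built into the simulation.

The geolocation loop closes the same way: `simulateTrack()` →
`simulateLight()` → `calibrateLight()` → `twoPassFit()` recovers a
noiseless stationary winter record with every day in the true 1° cell,
and a moving, 15%-shaded record with median error under two cells (see
`tests/testthat/test-acceptance.R`).

## Documentation

The methods vignette
(`vignettes/winter-connectivity-methods.Rmd`) documents the models,
parameter conventions (including which PCoA centering reproduces the
published percentages and which colony set the distance test uses),
numerical tie-breaks, and limitations.
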