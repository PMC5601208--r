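# forageEE

Trajectory-based analysis of the exploration–exploitation trade-off in
central-place foragers.

Seabirds and other central-place foragers alternate between two modes:
fast, directed *transit* (exploration for new resource patches) and slow,
tortuous *area-restricted search* (ARS; exploitation of a found patch).
forageEE takes raw GPS tracks — one fix every few minutes from a colony —
and asks, bird by bird and trip by trip, where the animal sits on that
continuum, whether its position is a stable individual trait, and what
drives it.

## What it computes

For a trip rediscretized to 1 km steps, the **first passage time** (FPT)
at a point is the time to cross a circle of radius *r* centred there. The
variance of log FPT across the trip, plotted against *r* over a 2–400 km
grid, peaks at the spatial scale of search — the **ARS scale**, used as
the *size of patch*. The FPT series at that scale is split into
homogeneous segments by a penalized change-point (Lavielle) segmentation
(dynamic programming over the Gaussian contrast
Σ nₛ log σ̂ₛ², segment count chosen by a normalized
contrast-decrease threshold); segments whose mean FPT exceeds the trip
mean are **ARS zones**. Each trip then yields four traits:

| trait | definition |
|---|---|
| time in patch | duration of a randomly selected ARS zone (h) |
| foraging effort | landings (maximal runs of steps < 10 km/h) in that zone |
| size of patch | ARS scale (km) |
| number of patches | ARS zones per trip |

The standardized traits are summarized by PCA; PC1 (oriented so time in
patch loads positively) is the **EE strategy score** — positive =
exploitation, negative = exploration — transformed as log(x + 2) for
modelling. Mixed models with bird and year random intercepts then give
repeatability *R* = v_bird / (v_bird + v_year + v_resid) with parametric
bootstrap CIs and boundary-corrected likelihood-ratio p-values, driver
tests (boldness, age, sex, age×sex; per-term LRTs, non-significant
interactions dropped), trip-metric associations and binary fitness GLMMs.

A correlated-random-walk simulator (`simulate_tracks()`) generates
GPS-like tracks, boldness tests and breeding outcomes with full ground
truth (phase labels, patch geometry, landing counts, variance components,
personality slopes), so every stage is testable offline.

## Worked example

```r
library(forageEE)

sim <- simulate_tracks(sim_config(n_birds = 12, trips_per_bird = 2,
                                  seed = 42),
                       dir = "demo/data")
cfg <- default_config(tracks_file  = "demo/data/tracks.csv",
                      boldness_file = "demo/data/boldness.csv",
                      breeding_file = "demo/data/breeding.csv",
                      out_dir = "demo/out", n_boot = 200, global_seed = 1)
res <- run_pipeline(cfg)

head(res$traits[, c("bird_id", "trip_id", "time_in_patch_h",
                    "foraging_effort", "size_of_patch_km", "n_patches")], 4)
#>   bird_id  trip_id time_in_patch_h foraging_effort size_of_patch_km n_patches
#> 1    B001 B001_T01        4.194924               1         10.12574         1
#> 2    B001 B001_T02       52.169529              40         21.58467         3
#> 3    B002 B002_T01       28.834135              18         26.79570         1
#> 4    B002 B002_T02       26.083505              22         26.79570         1
```

Each row is one trip: this bird's second trip spent 52 h in its selected
patch, landed 40 times there, searched at a 22 km characteristic scale and
used 3 patches. PCA pools such rows across the population:

```r
res$pca; round(res$variance_explained, 2)
#>             trait        PC1        PC2         PC3          PC4
#> 1   time_in_patch  0.6124491  0.3508521  0.06100250  0.705753190
#> 2 foraging_effort  0.6144784  0.3427791  0.05526243 -0.708424225
#> 3   size_of_patch  0.3729085 -0.5321961 -0.76004098  0.006658189
#> 4       n_patches -0.3290314  0.6900527 -0.64464135 -0.001794848
#> [1] 0.59 0.24 0.17 0.00
```

PC1 loads positively on time in patch, effort and patch size — the
exploitation pole — and explains 59% of trait variance in this simulated
population. Repeatability and boldness effects come from the mixed-model
layer (traits modelled on the log scale, standardized):

```r
print(res$repeatability, digits = 2)
#>          response    r ci_low ci_high     p v_bird v_year v_resid
#> 1         pc1_log 0.06  0e+00    0.64 0.420   0.06  0.000    0.94
#> 2   time_in_patch 0.40  1e-14    0.82 0.077   0.41  0.000    0.61
#> 3 foraging_effort 0.23  0e+00    0.76 0.214   0.23  0.000    0.78
#> 4   size_of_patch 0.26  0e+00    0.72 0.184   0.26  0.045    0.72
#> 5       n_patches 0.00  0e+00    0.53 0.500   0.00  0.072    0.96

print(res$drivers, digits = 2)
#>          response     term chisq df     p estimate   se
#> 1         pc1_log boldness  2.74  1 0.098    -0.32 0.19
#> 2   time_in_patch boldness  3.95  1 0.047    -0.42 0.20
#> 3 foraging_effort boldness  3.73  1 0.053    -0.38 0.18
#> 4   size_of_patch boldness  2.80  1 0.094    -0.34 0.19
#> 5       n_patches boldness  0.43  1 0.513     0.13 0.20
```

Time in patch is repeatable at R = 0.40 — this generator plants
bird-level variance 0.4 of a total 1.05 on log patch residence, so the
pipeline recovers the planted structure — and the negative boldness
estimates mean bolder birds exploit smaller patches for less time, the
direction planted by the default boldness slope of −0.13 on log patch
radius. Every table is also written as CSV under
`out_dir`, and `ee_cli(c("all", "--seed", "1", "--out", "run1"))` (or the
wrapper in `inst/scripts/forage_ee.R`) drives the same pipeline from a
shell.

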