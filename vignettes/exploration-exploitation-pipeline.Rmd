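---
title: "Quantifying exploration–exploitation strategies from central-place foraging tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying exploration–exploitation strategies from central-place foraging tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

forageEE turns raw GPS fixes from a central-place forager — the motivating
system is a large pelagic seabird tracked from its breeding colony — into a
per-trip description of where the animal sat on the exploration–exploitation
continuum, and then into the population-level statistics that behavioural
ecologists ask of such data: are the trip-level foraging traits correlated
into a strategy axis, is that axis repeatable within individuals, is it
driven by personality, age or sex, and does it predict breeding success?

This vignette explains the models and procedures, the tunable parameters and
their defaults, what the synthetic track generator does and does not
emulate, and the numerical choices and limitations a user should know about.

## 1. From fixes to a first-passage-time profile

A *trip* is the ordered sequence of fixes between leaving and returning to
the colony. Three cleaning steps precede any behavioural inference:

1. **Nest removal.** Fixes within `colony_radius_km` (default 2 km) of the
   colony are discarded. The radius is a package choice: the data model only
   says points "at the nest" are removed, and 2 km comfortably excludes the
   island while costing a negligible sliver of at-sea track at typical
   transit speeds.
2. **Drift (speed) filter.** A bird sitting on the water drifts slowly and
   tortuously with the currents; left in place, drift mimics
   area-restricted search. Every fix whose arriving step is slower than
   `speed_filter_kmh` (default 10 km/h, exclusive) is removed. The rule is
   applied once, to the observed consecutive steps: a step that bridges a
   removed drift run is not re-examined. `speed_filter(iterate = TRUE)`
   re-applies the rule to a fixed point — that variant is idempotent by
   construction, but erodes genuine flight fixes adjacent to long drifts,
   so the one-pass rule is the default. The removed slow periods are not
   lost: they are exactly the *landings* counted later.
3. **Rediscretization.** First passage time is only meaningful on a track
   with equidistant points. Points are placed every `step_km` (default
   1 km) of cumulative along-track distance, interpolating positions
   linearly within each original segment in a local equirectangular chart
   about the segment midpoint latitude, and times linearly in distance.
   Segments are at most a few tens of km, so planar interpolation errs by
   far less than the step itself. Note the equidistance is along-track: a
   1 km window that spans a sharp turn has a chord slightly shorter than
   1 km. All distances use the haversine great-circle formula on a sphere
   of radius 6371 km; ellipsoidal corrections are irrelevant at a 1 km
   step.

The *first passage time* (FPT) at a path point is the time the bird takes to
cross a circle of radius $r$ centred there: the interval between the
backward and forward first crossings, with each crossing instant linearly
interpolated inside the straddling step. Points whose circle is never
exited on one side (track start/end inside the circle) are undefined and
excluded, never imputed. `fpt_profile()` evaluates this over a grid of 50
logarithmically spaced radii from 2 to 400 km (`fpt_radii_*` config keys):
the range brackets everything from sub-mesoscale searching to the scale of
a whole foraging trip, and log spacing resolves the small scales where
area-restricted search actually happens.

Fast directed transit gives uniformly small FPT; slow tortuous search gives
large FPT. The variance of log FPT across the track therefore peaks at the
radius that best separates the two modes, and that argmax radius is the
**ARS scale** — interpreted as the characteristic **size of patch** for the
trip. Natural logs are used (the argmax is base-invariant); a radius needs
at least `fpt_min_defined = 5` defined FPT values for its variance to
count, which stops end-of-track effects from dominating; the variance curve
is not smoothed before the argmax and ties break toward the smaller radius,
so the statistic is deterministic.

## 2. Segmenting the track into ARS zones

The FPT series at the ARS scale is piecewise-homogeneous: long stretches of
low mean/low variance (transit) alternate with stretches of high mean/high
variance (search). The package re-implements the Lavielle
penalized-contrast segmentation: for each candidate number of segments
$k \le$ `seg_kmax`, dynamic programming (in C++) finds the partition
minimizing the Gaussian contrast $\sum_s n_s \log \hat\sigma^2_s$ over
segments of at least `seg_lmin` points, with within-segment ML variances
floored at $10^{-8}\,\mathrm{var}(\text{series})$ for numerical safety. The
number of segments is chosen by the normalized second-difference rule: the
contrast curve $J(k)$ is rescaled to decrease from `seg_kmax` to 1, and the
chosen $k$ is the largest whose decrease $D(k)$ exceeds
`seg_threshold_S = 0.75`. The defaults (`seg_kmax = 30`, `seg_lmin = 5`
points = 5 km of path, $S = 0.75$) are the reference defaults of the
segmentation literature; they are deliberate package choices, exposed in
the configuration, and patch counts are sensitive to them — the threshold
rule is conservative and will sometimes merge two patch visits separated by
a short commute into one segment.

Undefined FPT entries inside the series (short end effects) are filled by
linear interpolation before the DP, which requires a complete series; the
filled positions are flagged and the original undefined values are still
used for classification means.

A segment is an **ARS zone** when its mean FPT is strictly greater than the
mean over the whole trip; ties go to non-ARS. Zones are mapped back to real
time through the interpolated path times of their boundary points, giving
**time in patch** (entry to exit, in hours). **Foraging effort** is the
number of landings in a zone: a landing is a *maximal run* of consecutive
raw steps slower than 10 km/h — a multi-fix sit on the water is one event —
assigned to the zone containing the run's midpoint, so boundary-straddling
runs are attributed unambiguously. Landings are counted on the raw,
unfiltered trip, because the slow fixes removed before FPT are precisely
the on-water periods. The number of zones per trip is the **number of
patches**.

Because trips differ in zone count, the per-trip trait vector takes time in
patch and foraging effort from *one* zone selected uniformly at random.
The selection is seeded per trip from `(global_seed, trip_id)`, so adding
or removing trips never reshuffles other trips' draws and a pipeline rerun
is byte-identical.

## 3. The EE strategy score and its statistics

The four traits — time in patch, foraging effort, size of patch, number of
patches — are standardized (mean 0, SD 1) and summarized by:

* **Pairwise Pearson correlations** (pairwise-complete, two-sided t-based
  p-values) to show whether the traits cohere into a trade-off.
* **PCA on the correlation matrix** (complete cases; at least 5 rows). PC1
  is the **EE strategy score**; its sign is fixed so the time-in-patch
  loading is positive, making positive scores mean exploitation and
  negative mean exploration. For modelling, the score is transformed as
  $\log(x + 2)$; scores at or below $-2$ (possible in principle, since PC1
  is unbounded) are clipped to a $10^{-6}$ floor with a warning rather than
  failing.
* **Boldness scores** from standardized approach tests scored 0–4 (no
  response … stands up; the per-test score is the maximum behaviour
  shown). Observer identity and observation number are known to shift
  scores, so a linear model with additive observer, observation-number and
  bird terms is fitted and the per-bird coefficients are mean-centred over
  birds. Bird-as-fixed-coefficients is the default reading; a
  random-intercept alternative (`method = "random"`) is provided because
  the two readings differ only by shrinkage and either might be preferred
  at very unequal test counts.

Population-level inference uses linear mixed models with bird-identity and
year random intercepts (lme4 is the engine throughout; grouping factors
with a single observed level are dropped with a message). Trait responses
enter these models on the log scale — `log` for time in patch and size of
patch, `log(x+1)` for the two counts — then standardized, so estimates are
reported on the logged scale; durations and scales are log-normal-like and
raw-scale modelling would let a few long patch residences dominate the
variance decomposition. The correlation and PCA layer, by contrast, uses
the raw traits.

* **Repeatability** $R = v_{bird}/(v_{bird} + v_{year} + v_{resid})$ from a
  REML fit. The year variance sits in the denominator by default — the
  grouping-factor-adjusted convention — with `include_year = FALSE`
  available, because published variance-component tables are not always
  reconstructible under a single convention. Confidence intervals come
  from a parametric bootstrap (simulate from the fitted model, refit,
  recompute $R$; percentile interval; default 1,000 iterations) and the
  p-value from a likelihood-ratio test of $v_{bird} = 0$ against the
  boundary null, $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$.
* **Driver tests** regress each response on boldness, age, sex and
  age×sex. Fits are by full maximum likelihood and every term is judged by
  a likelihood-ratio comparison of models with and without it (1 df); a
  non-significant interaction ($p \ge 0.05$) is dropped and main effects
  are reported from the reduced model.
* **Trip-metric associations** fit the transformed strategy score on trip
  duration, total distance and maximum range one metric at a time — the
  three covary too strongly to enter jointly.
* **Fitness models** are binomial GLMMs of breeding success (0/1) on one
  trait at a time, again because the traits covary; a fitted |log-odds
  slope| above 15 aborts with a separation diagnostic.

## 4. What the synthetic generator emulates — and what it does not

`simulate_tracks()` provides ground truth for every stage: per-fix phase
labels (colony / transit / patch / landing), patch centres, radii and visit
intervals, per-patch landing counts, each bird's latent boldness and random
intercept, and the year effects. Its defaults describe a plausible
Southern Ocean central-place forager: fixes every 15 min from a colony at
46°S 51°E; directed transit at 45 km/h with small wrapped-normal heading
noise; tortuous search at 20 km/h with heading SD 1.2 rad inside circular
patches of 30 km baseline radius, 80–250 km apart; log-normal patch
residence around 8 h with variance components
$v_{bird} = 0.4, v_{year} = 0.05, v_{resid} = 0.6$ on the log scale;
Poisson landings (1.5/h in patch, 0.1/h in transit) as 30-min drift runs at
2 km/h; per-bird patch radius scaled by $e^{\beta \cdot boldness}$ with
$\beta = -0.13$; observation jitter SD of 0.03 km. Trips average a
few days — compact enough to iterate on while containing every structural
feature the pipeline consumes (two-mode movement, landings, colony
departure and return).

Two generator details are deliberate departures from the most literal
construction, both for ground-truth crispness. At the patch boundary the
heading is redrawn until a full-length step stays inside, rather than
reflecting the step radially: radial reflection occasionally shortens a
step below the 10 km/h drift threshold and plants a spurious "landing"
that no detector should be blamed for missing. Likewise each landing run
is followed by at least one ordinary fix, so planted runs are exactly the
maximal slow runs the landing counter is defined on.

What the generator does **not** emulate: location error beyond small
jitter, gaps and duty-cycling, wind and current fields, prey-field
structure, fishing-vessel attraction, or any habitat preference. Landing
rates are also constant across birds and patches, which makes the
simulated foraging-effort trait nearly proportional to time in patch
(their correlation approaches 1 in generated populations, where real data
would show independent variation in landing rate). Passing the
simulation-based tests therefore shows the pipeline recovers the
behavioural structure it models — not that real tracks satisfy those
modelling assumptions.

A known limitation found while validating: the recovered ARS scale
responds to the planted patch radius only up to the radius the bird's
search footprint actually fills (with the default speeds and residence
times, roughly 30 km; larger patches are under-covered and the scale
saturates). Consequently the boldness→patch-radius effect, which shifts
radii by only ±13% per SD, transfers weakly to the recovered size-of-patch
trait, and detecting its sign reliably needs far more birds than a typical
deployment. The mixed-model layer recovers a directly planted −0.13 slope
to within ±0.03 (see the test suite); the attenuation is upstream, in the
scale statistic itself.

## 5. Numerical choices and reproducibility

* Haversine distances on a 6371 km sphere; coordinates validated on entry.
* Crossing instants, rediscretized positions and times are linear
  interpolations; the rediscretization endpoint uses a $10^{-7}$ relative
  epsilon so a path of length $n \cdot$`step_km` yields $n+1$ points.
* The segmentation variance floor is $10^{-8}\,\mathrm{var}(series)$; an
  exactly constant series short-circuits to one segment.
* Optimizer defaults of lme4 are used; singular fits (a variance estimated
  at zero) are accepted silently, since boundary estimates are routine in
  variance-component work. Bootstrap refits that fail are dropped and
  counted.
* All randomness flows from explicit seeds: the generator from
  `sim_config(seed=)`, zone selection from `(global_seed, trip_id)`, the
  bootstrap from its `seed` argument. Reruns are byte-identical.
* Problem sizes used by `scripts/acceptance.R`: 40 birds × 2 trips under
  generator defaults with 500 bootstrap iterations — the package's
  reporting choice, large enough that every stage runs on realistic
  volumes.

## 6. Open design decisions

The data model leaves several choices open, resolved here as follows: the
ARS scale is computed per trip (a pooled option across trips would weight
long trips more; per-trip matches the per-trip trait construction);
repeatability models are intercept-only (trait values enter standardized,
and the driver analysis is a separate, explicitly fixed-effects question);
the colony-exclusion radius, the one-pass speed filter and the landing
run/midpoint rules are as described above, each exposed as configuration
so a sensitivity analysis is one config edit away.
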