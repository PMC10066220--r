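---
title: "Methods: from biologging and echosounder samples to season contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from biologging and echosounder samples to season contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pengkrill)
```

This vignette explains the models and procedures behind `pengkrill`: how
foraging effort of a central-place forager is derived from GPS and
time-depth-recorder (TDR) data, how krill availability is derived from
echo-integrated acoustics, how the two are contrasted between breeding
seasons, and which design choices were genuinely open and how they were
resolved.

## The analysis problem

Breeding chinstrap penguins are central-place foragers: every foraging trip
starts and ends at the nest, so foraging effort (trip duration and
distance, diving rates, prey-capture attempts) responds directly to how
much prey is available, how deep it sits, and how it is spatially
organised within the colony's foraging range. The pipeline quantifies both
sides — penguin effort from biologging, krill availability from
fisheries-acoustics transects, conditions from gridded environmental
fields — and asks, endpoint by endpoint, whether two seasons differ.

## Trips

Raw GPS tables are processed in three steps:

1. **Speed filter** (`speed_filter()`, default 10 m/s): a forward pass that
   removes any fix whose great-circle speed from the last retained fix is
   implausible, recomputing speeds from the retained predecessor. The
   forward-pass variant guarantees that no consecutive retained pair
   exceeds the bound — a property the tests assert.
2. **Interpolation** (`interpolate_track()`, default 300 s): linear
   interpolation of longitude and latitude onto an exact 5-min lattice
   anchored at the first fix, with no extrapolation. Linearity is adequate
   at sub-40-km scales; no spline is used. We filter *before*
   interpolating so that the lattice heals the gaps left by removed
   outliers; interpolating first would let a removed fix punch a hole back
   into the lattice and split trips spuriously. Both operations are
   exposed separately, so the opposite order can be run by hand.
3. **Segmentation** (`segment_trips()`): fixes within 250 m of the colony
   are dropped; the remainder splits at temporal gaps longer than one
   sampling interval; runs of 1 h or less are discarded.

All distances are haversine on a 6371 km sphere (`geosphere`). Trip
metrics are duration (h), cumulative distance (km) and maximum range (km).

## Dives

TDR series (1 Hz) are zero-offset corrected before detection
(`zero_offset_correct()`): the series is cut into blocks (default 1800 s),
the 10 % quantile of each block estimates the local surface baseline, and
the linearly interpolated baseline is subtracted. This tracks both
constant offsets and slow sensor drift, provided each block contains at
least ~10 % surface time — true of penguin series, which alternate dives
with surface intervals. The block quantile is a deliberate simplification
of more elaborate surface-detection schemes; its residual error (a few
centimetres) is negligible against the 3 m detection threshold.

Dives are maximal runs deeper than 3 m (`detect_dives()`); the threshold
is configurable since devices and species differ. Phases are segmented by
the span rule (`segment_phases()`): the bottom phase runs from the first
to the last sample at ≥ 80 % of maximum depth (the convention of standard
dive-analysis software), descent before, ascent after. Bottom duration is
counted in samples, so a V-shaped dive has a 1 s bottom. A dive is
**complete** when its bottom lasts at least 5 s (`classify_complete()`,
boundary inclusive) — an operationalisation of "a dive with a bottom
phase", which the data themselves cannot pin down more precisely.

**Wiggles** (`count_wiggles()`) are upward excursions of the depth trace
during the bottom phase: local depth minima whose depth drops by at least
1 m on *both* flanks before the trace rises back above them (a prominence
rule, computed on plateau-compressed samples). Prominence-based counting
is monotone in the threshold — raising the minimum amplitude can only
reduce the count — and exactly recovers the constructed wiggle count of
synthetic dives, which the acceptance tests exploit as an oracle.

Per-trip metrics: frequency of complete dives and cumulative dive duration
are computed over **all** dives; mean dive duration, mean and maximum
bottom depth and capture effort (wiggles per dive) over **complete** dives
only, since bottom statistics and wiggles are defined within bottom
phases. This choice also keeps the shallow incomplete spike-dives from
contaminating depth endpoints.

## Krill acoustics

`echo_integrate()` sums cleaned sample densities into half-open 0.5 nmi ×
5 m cells (NASC, m² nmi⁻²) down to 500 m, conserving total density to
floating-point accuracy. From the cell grid:

* `vertical_profile()` — stratum mean ± s.e. across along-track bins;
* `swarm_depth_selection()` — depths of cells above the first quartile of
  positive cell NASC (type-7 linear interpolation, R's default; a numeric
  threshold can override it);
* `aggregation_by_depth()` — per-stratum Ripley's K aggregation.

**Ripley's K.** For each stratum the along-track midpoints of detection
cells (NASC > 0) are treated as a 2-D point pattern on the transect line
inside a rectangular corridor (transect length plus a one-cell buffer,
corridor height one along-bin by default). `ripley_k_stratum()` computes
the isotropic-corrected estimator with edge weights equal to the inverse
fraction of each pair's circle inside the window, evaluated numerically at
360 circle points; when every point is farther from the boundary than the
largest radius the weights are exactly 1 and the estimator reduces to the
naive double sum, which the tests verify to 1e-9. In very elongated
windows the circle fraction is floored at 1/360 to avoid infinite weights.
The aggregation index is the unweighted mean of `K_iso(r) − πr²` over the
radii grid: positive = aggregated, ≈ 0 = random, negative = dispersed.

Two radii conventions coexist. Stand-alone `ripley_k_stratum()` defaults
to 10 radii up to a quarter of the shorter window side (the standard
point-pattern heuristic). `aggregation_by_depth()` instead defaults to 10
radii up to three along-track bins (≈ 2.8 km at 0.5 nmi bins): swarm
clustering operates at the scale of a few sampling bins, and at radii much
longer than the cluster scale the index is dominated by between-stratum
sampling noise rather than aggregation signal. Strata with fewer than 5
detection cells get an undefined index rather than a noisy one. Whether
the original field analyses ran in 2-D geographic space or along-transect
distance is not recoverable; the corridor construction covers both
readings for effectively collinear survey designs.

## Season contrasts: PERMANOVA

Every endpoint is compared between seasons with a one-way PERMANOVA
(`permanova()`), written from scratch on squared Euclidean distances of
z-scored features (`standardize_features()`): with
`SS_total = Σ_{i<j} d²_ij / N` and
`SS_within = Σ_g Σ_{i<j∈g} d²_ij / n_g`,

```
pseudo-F = ((SS_total − SS_within) / (a − 1)) / (SS_within / (N − a)),
```

and the p-value is `(1 + #{F_perm ≥ F_obs}) / (1 + n_perm)` under
unrestricted label permutation (999 by default), so p is never 0 and has
resolution 1/(n_perm + 1). Euclidean distance after z-scoring makes the
univariate pseudo-F algebraically identical to the classical one-way
ANOVA F — the package's strongest oracle, asserted to 1e-10 — and the
implementation is cross-checked against `vegan::adonis2()` in the tests
(vegan is never used as the implementation). Endpoints are tested
per-variable (univariate), matching the single-degree-of-freedom contrasts
a reader expects; the multivariate path exists through the
`cbind(...) ~ group` formula interface. p-values across the many endpoints
are reported unadjusted.

## Environment and breeding

`extract_radius()` keeps 5-km cells whose centres lie within 75 km of the
colony (centre-in-radius, not area-weighted — the radius is two orders of
magnitude larger than a cell, so the difference is a boundary sliver).
`seasonal_means()` averages months within the austral windows: Nov–Jan for
chlorophyll, PAR and wind; Jun–Sep of the immediately previous winter for
sea-ice cover (so season "2021/22" uses Jun–Sep 2021).
`monthly_climatology()` gives the per-calendar-month mean ± sd across
years for long-term series; it is a descriptive table only — no
peak-timing inference is attempted, because monthly resolution cannot
support it. Breeding success is chicks at crèche divided by nests at
incubation, per sub-colony.

## The synthetic-data generator

`simulate_bundle()` generates every pipeline input under a
`season_scenario()`, with two presets:

* `scenario_good()` (a 2019/20-like season): 17 birds × 5 trips, trip
  duration ~ Gamma(mean 10 h), 85 % complete dives, wiggle rate 6,
  krill mode 45 m in dense tight swarms (0.35 parents/km, ~45 samples per
  swarm, 0.35 km spread), biomass ×1.5, CHL 1.4 mg m⁻³, wSIC 0.55,
  wind 5.5 m s⁻¹, breeding success 1.05 chicks/nest.
* `scenario_poor()` (2021/22-like): 10 birds, trips ~ 14 h, 60 % complete
  dives, depth-coupled wiggle rate (base 13 scaled by a trip-depth
  availability weight, effective ≈ 8.5), krill mode 90 m in small
  dispersed swarms (1.6 parents/km, ~4 samples per swarm, 2 km spread),
  biomass ×0.6, CHL 0.7, wSIC 0.25, wind 7.5, success 0.75.

The tagging effort (27 birds, ~135 trips), the 35 km range cap, the 133 m
depth cap, the 2–17 wiggle range, the ~1.4× breeding-success contrast and
the month windows are the study conditions the generator emulates; where
the field study pins no value (track model, swarm process, behavioural
coupling) the generator uses the simplest structure with the right
qualitative behaviour:

* **Tracks** are out-and-back correlated random walks at ~1.6 m/s with an
  outbound bias, a meandering middle, and a homing phase timed to hit the
  drawn duration; range is hard-capped. Fix gaps (3 %) and displaced
  outlier fixes (1 %, 6–10 km) exercise interpolation and the speed
  filter. Only trip-level summaries feed the analysis, so no habitat
  model is implied.
* **Dive depth** is hierarchical: each trip draws a target depth (a
  two-component normal mixture whose bulk is shifted so the season mean is
  identical across scenarios), and complete dives add a gamma deviation
  around it. The poor season gets the same mean but a much heavier deep
  tail (gamma shape 1.8 vs 9), which reproduces a deeper *maximum* with an
  unchanged *mean* bottom depth — the pattern the season contrast is
  designed to show. Incomplete dives are shallow fast V-dives (5–12 m)
  whose bottom span stays below the 5 s completeness threshold by
  construction.
* **Wiggles** per complete dive are Poisson, clipped to [2, 17], with the
  poor season's rate scaled by a trip-depth availability weight so effort
  concentrates in deeper trips (krill sits deep); consequently the
  wiggle-weighted centre of mass of the effort profile — not necessarily
  its modal 5-m stratum, which season-matched mean depths pin in place —
  sits deeper in the poor season, and that is what the tests assert.
* **Krill fields** are Thomas cluster processes along the transect:
  Poisson parents, Gaussian offspring horizontally and in depth (swarm
  centres Gaussian around the mode), lognormal per-sample densities. The
  dispersed poor field uses many small wide clusters, which at the cell
  level is nearly indistinguishable from randomness — hence a lower
  aggregation index.
* **Environmental grids** are i.i.d. Gaussian around scenario means on the
  5 km lattice; no spatial autocorrelation is modelled, so PERMANOVA's
  treatment of cells as replicates is exactly satisfied in the synthetic
  world (in real fields autocorrelation would inflate the effective
  significance — a caveat for interpreting the environmental p-values).
* **Breeding counts** are binomial with a two-egg clutch.

Every component draws from its own sub-seed of the scenario seed, so
identical scenarios give byte-identical bundles regardless of which
components are generated, and the whole pipeline is a deterministic
function of (scenarios, seed).

What passing tests show — and what they do not. The generator reproduces
the *directions* of the season contrasts and the marginal ranges of the
measurements; it does not attempt mechanistic krill–predator coupling,
spatially autocorrelated environments, sea-ice dynamics, tides or
bathymetry. Effect *sizes* on synthetic data are design choices, not
predictions, and nothing here validates the pipeline against field-scale
measurement error in GPS or pressure sensors beyond the simple noise
models above (12 m track jitter, 3 cm depth noise, 0.4–0.7 m drifting
surface offset).

## Numerical choices and degenerate inputs

* Quantiles are type-7 (R default) everywhere a quantile is taken.
* The completeness boundary (bottom exactly 5 s) counts as complete; the
  trip filter boundary (exactly 1 h) is discarded.
* Zero-variance features abort standardisation with the column named;
  `SS_within = 0` yields an infinite pseudo-F with the smallest resolvable
  p.
* Empty inputs return empty, typed results (empty sample table → all-zero
  grid; all-zero grid → empty swarm selection with a warning, undefined
  aggregation per stratum; zero dives → zero metrics with `NA` frequency).
* Strata with fewer than 5 detection points, and standard errors with a
  single along-track bin, are reported as `NA` rather than extrapolated.

## Problem sizes

The shipped configuration uses 27 birds (135 trips, ~24 000 dives at 1 Hz),
a 40 nmi transect (80 × 100 NASC cells), 1089 environmental cells per
month and 12 sub-colonies per season; the test suite exercises the same
code on smaller scenarios (2 birds, 4 trips) where distributional claims
are not at stake. Calibration experiments use 100 random tables for the
ANOVA identity, 500 replicates for the type-I error of the permutation
test, 200 CSR and 100 Thomas patterns for Ripley's K, and 1000 synthetic
dives for the wiggle oracle.

## Known limitations

* The speed filter's forward pass can retain an early outlier and drop
  subsequent good fixes in pathological tracks; with 5-min cadence and
  10 m/s this does not arise in practice.
* The isotropic correction is evaluated numerically (360 arc points); in
  extremely elongated corridors individual pair weights are coarse,
  although the stratum index remains well calibrated under CSR.
* PERMANOVA assumes exchangeability under the null; spatially or
  temporally autocorrelated observations (environmental cells, adjacent
  trips of one bird) violate it in real data, and p-values there should be
  read as descriptive.
* The wiggle definition (1 m prominence) is a convention; capture-effort
  contrasts are robust to the threshold, absolute counts are not.
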