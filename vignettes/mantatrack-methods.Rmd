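---
title: "Methods: residency, presence modelling and geolocation in mantatrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residency, presence modelling and geolocation in mantatrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mantatrack)
```

mantatrack analyses passive acoustic telemetry from a coastal receiver
array together with archival satellite-tag geolocation, following the
analysis design of a two-year reef manta ray monitoring programme in
Dungonab Bay (Sudanese Red Sea). This vignette documents the models, the
tunable parameters and their defaults, the numerical choices, what the
synthetic-data generator does and does not emulate, and the package's known
limitations.

## Data model and time handling

Detections (`tag_id`, `receiver_id`, UTC timestamp) are stored sorted by
`(tag_id, timestamp, receiver_id)` — a deterministic total order so that
every scan over the data is reproducible even with tied timestamps.
Calendar-day operations (daily presence, residence index, day-of-year
covariates) apply a configurable fixed UTC offset, default **+3 h** (local
time on the Sudanese coast). Archived acoustic exports carry UTC only, and
no day-boundary convention is recorded with them, so the boundary is an
explicit, configurable analysis parameter rather than a hidden constant.

Great-circle distances use the haversine formula on a sphere of radius
6371 km. At receiver-to-receiver scales (1–29 km) the difference from an
ellipsoidal model is far below the positional uncertainty of an acoustic
detection, so an ellipsoid would add complexity without information.

## Detection quality control

Three filters run in a fixed order, and every input record is attributed to
exactly one removal stage or retained (a *conservation identity* asserted
at run time):

1. **Isolated singles.** A detection is removed iff no other detection of
   the same tag occurs anywhere in the array within ±60 min. The window is
   not dictated by the source analysis; ±60 min matches the 1-h timeout
   scale used for residency events and is configurable. Offshore stations
   are exempt: tag density there is so low that signal collisions are
   unlikely, and lone records are informative evidence of long-distance
   movement.
2. **Post-release exclusion.** Detections within 48 h of tagging release
   (exact timestamps, not calendar days) are removed to avoid analysing
   capture-associated behaviour.
3. **Speed filter.** Scanning each tag's sequence, whenever consecutive
   detections at *different* receivers imply a straight-line speed above
   2 m/s, the **later** record is removed and the scan re-evaluates against
   the surviving predecessor. Removing the later record preserves the
   already-validated earlier track; `drop = "both"` is available. Distances
   are straight-line between receivers, ignoring land.

A removal can itself create a new isolated single (its only neighbour is
gone) or expose a new speed violation, so the three-stage cascade repeats
until a pass removes nothing (two passes in practice). This makes the full
QC **idempotent**: running it on its own output removes nothing, a property
the test suite asserts. Stage attribution is unaffected — each record keeps
the stage that removed it.

**Daily presence** requires ≥ 2 retained detections of an animal within one
local calendar day.

## Residency statistics

The residence index is `RI = detection_days / track_days` with
`track_days = last − first + 1` (both endpoint days counted). The inclusive
span is the variant that reproduces the published per-animal ratios
(e.g. 352/702 → 0.50); an exclusive-span option exists.

Residency events open on the *second* consecutive detection of an animal at
the same receiver (a single detection opens nothing; an intervening
other-receiver detection resets the candidate) and close on a receiver
switch or when 60 min pass without a detection; the event end is the last
member detection. The implementation is validated against an independent
state-machine replay on random sequences.

Movement networks count directed transitions between consecutive distinct
receivers per animal; receivers with zero detections remain as isolated
nodes, and an undirected collapse is provided for plotting. Group
comparisons use Welch's unequal-variance *t*-test (RI by sex) and Pearson
correlations (wingspan vs detections / RI) with Shapiro–Wilk and Levene
diagnostics; degenerate groups are flagged and skipped rather than tested.

## Hourly presence model

The response is binomial: animal-hour `y = 1` iff ≥ 1 retained detection in
that hour, built for every animal from 48 h after release to the end of the
study window. Covariates are joined by local date: day-of-year, hour,
lunar illuminated fraction, chlorophyll-a, the number of active receivers
(computed per hour from station activity intervals, which reduces to the
daily value when intervals only change at day resolution), sex and
maturity.

The linear predictor (logit link — the conventional choice for a binomial
GAMM; the source analysis does not state its link) is

    η = β₀ + f_day(doy) + f_hour(hour) + f_moon(moon) + f_chla(chla)
        + β_sex + β_mat + β_ns·nStations + b_animal

* `f_day`, `f_hour`: **cyclic cubic regression splines** (k = 7; periods
  365 and 24) built from the value/second-derivative parameterisation with
  value, first- and second-derivative continuity at the wrap, giving k − 1
  free coefficients and the exact curvature penalty
  `∫ f″² = βᵀ Dᵀ B⁻¹ D β`. The basis is verified against
  `stats::spline(method = "periodic")` and the penalty against numerical
  integration of the squared second derivative.
* `f_moon` (k = 6), `f_chla` (k = 7): natural cubic regression splines with
  equally spaced knots over the observed range, linear extrapolation
  beyond it.
* Each smooth is centred by absorbing the sum-to-zero constraint
  (orthonormal null-space reparameterisation), keeping it identifiable next
  to the intercept.
* `b_animal`: per-animal random intercept implemented as a ridge-penalised
  indicator block — the standard mixed-model-as-penalised-GLM equivalence.
* The study spans November 2012 – October 2014, which contains no
  February 29, so day-of-year is 1–365 with a guard mapping 366 → 365.
* `nStations` enters linearly: it is an effort covariate with a
  monotone expected effect, and the per-hour counts take few distinct
  values.

Fitting is penalised IRLS (deviance-change convergence, tolerance 1e-8,
≤ 50 iterations; non-convergence is an error). Smoothing parameters —
one per smooth plus the random-effect ridge — are selected by
coordinate-descent grid search (default grid 10⁻²…10⁷, two sweeps,
warm-started) minimising the deviance GCV score `n·D / (n − edf)²`. GCV was
chosen over REML for transparency and reproducibility; the criterion and
grid are arguments. Effective degrees of freedom are the trace of the
influence matrix `(XᵀWX + S_λ)⁻¹ XᵀWX`, and the reported AIC is the
**conditional** variant `D + 2·edf`. Per-term p-values are approximate Wald
chi-square statistics on the block coefficients with `edf` degrees of
freedom — adequate for screening, not exact.

Model selection fits all 2⁴ = 16 subsets of the four smooths (fixed effects
and the random intercept always included) and ranks by AIC. The published
selected-model deviance explained (10.9%) is **not** a quantitative target
here: it depends on the fitting package's basis parameterisation, AIC
variant and smoothing criterion in ways that cannot be replicated without
the raw data. What the test suite does assert, on synthetic data with known
truth, is (i) the fitted seasonal smooth correlates r > 0.9 with the
generating curve at ~50,000 animal-hours, (ii) the AIC-best model contains
the generating smooth set in ≥ 80% of replicates, and (iii) the fit agrees
with an independent GAMM implementation (mgcv) on shared data over the
observed covariate range.

For the replicate selection study the tables use 10 animals × 120 days.
Synthetic chlorophyll is itself seasonal, so with `f_day` in the model the
chlorophyll term is identified only through the *non-seasonal* component of
the series; smaller tables leave that component too weak for reliable
selection, and this size gives adequate power while staying inside the
suite's run-time envelope.

## Space use

Centres of activity (COAs) are detection-count-weighted means of detecting
receiver positions in 360-min bins aligned to local midnight (720-min bins
for the geolocation fusion). COAs are pooled across animals by calendar
month (both study years pooled) and a kernel utilisation distribution is
fitted per month with ≥ 5 COAs.

The KUD is a bivariate Gaussian product kernel on a **local tangent-plane
projection** centred on the pooled-COA centroid — the bay spans well under
a degree, so planar distortion is negligible and contour areas are
well-defined in km². The bandwidth is the reference rule
`h_ref = mean(σ_x, σ_y) · n^(−1/6)` (isotropic normal-reference plug-in);
the grid is 100 × 100 cells over the COA bounding box padded by `3·h_ref`;
the density is renormalised to unit mass on the grid, and the q% contour
threshold is the largest density level whose superlevel set holds ≥ q% of
the mass. Mass conservation (tolerance 1e-6) and 50% ⊆ 95% nesting are
asserted for every fitted month. Contours are not clipped to water, so
areas may overlap land.

## Gridded HMM geolocation

States are water cells of a 0.25° grid. The reference implementation used
by the source analysis is proprietary; this module implements the described
structure — daily diffusion at an a-priori 2 m/s speed, light- and
SST-based likelihoods, bathymetric masking, acoustically fixed positions —
with explicit Gaussian observation models, as a faithful open analogue
rather than a clone.

* **Transition kernel**: Gaussian in great-circle distance, hard-truncated
  at 2 m/s × 86,400 s = 172.8 km/day and row-normalised over water. The
  diffusion scale σ = 172.8/√(2 ln 100) km puts 99% of unconstrained daily
  mass inside the speed bound, so the truncation trims only the tail.
* **Observation model**: independent Gaussians for the light-based
  longitude estimate (default σ = 1°, the typical accuracy class of
  light-based geolocation) and for tag SST against a smooth SST field
  (default σ = 0.5 °C), multiplied by the water mask. Latitude information
  enters only through the SST gradient — deliberate equinox-adjacent
  realism, and the reason posteriors are anisotropic (wider in latitude).
* **Fixed days**: days with a 12-h acoustic COA clamp the *filtered*
  distribution to a delta at that cell; the constraint propagates through
  smoothing.
* **Inference**: scaled forward–backward smoothing (per-step
  renormalisation guards underflow; the scaled recursion is verified
  against a dense unscaled matrix-product oracle to 1e-8 on 15 × 15
  grids) and a joint Viterbi decoder restricted to the kernel support,
  with per-day posterior modes and 95% highest-posterior-density areas.

## The synthetic-data generator

The generator reproduces the *statistical structure* the pipeline assumes,
with full ground truth:

* **Array**: 15 in-bay stations in five regions (≥ 1 km spacing, the two
  furthest 29 km apart) plus offshore stations ~70 and ~125 km away;
  three receivers stop early in long runs, emulating battery failure and
  driving the `nStations` effort covariate.
* **Tags**: transmission gaps i.i.d. uniform(310, 410) s; detection is
  logistic in distance with p(540 m) = 0.5, and the slope is set by the
  zero-range probability `p_max = 0.95`, which places p ≈ 0.05 at 1080 m.
  The 50% range matches range testing in comparable Red Sea reef
  environments; the slope is a configuration knob because only the 50%
  point is known.
* **Presence**: daily in-bay presence follows a logit model on a cyclic
  day-of-year term (peak day 288, i.e. mid-October), chlorophyll-a anomaly
  and moon fraction, with coefficients chosen so daily probabilities span
  roughly 0.2 (late winter) to 0.75 (fall), the seasonal range reported
  for the monitored cohort. Day-to-day persistence is a probit-threshold
  AR(1) (ρ = 0.95): the configured marginal probability is preserved
  exactly while absences form the multi-week runs seen in long acoustic
  records rather than daily coin flips.
* **Movement**: a mean-reverting biased walk whose target is an anchor
  station drawn daily from seasonal region weights (fall central, winter
  north — where a single station sits — spring south, summer channel),
  with within-day anchor switches producing between-receiver movements and
  a winter dispersion multiplier producing the winter-enlarged home ranges.
  Station-anchored dwelling mirrors aggregation/cleaning-site behaviour and
  keeps detection series dense at one receiver at a time. Per-step
  displacement is hard-capped at 2 m/s (with a 0.1% margin so the bound
  also holds for the great-circle step length after unprojection). Absent
  animals head to an offshore holding point 40 km east.
* **Noise**: collision artefacts duplicate a genuine detection at a
  receiver ≥ 5 km away within seconds (removable by the speed filter);
  isolated false detections appear at low rate on absent days (removable
  by the singles filter). At default rates the QC recovers ≥ 95% of
  labelled noise while losing < 1% of genuine detections.
* **Environment**: moon fraction is a 29.53-day sinusoid; chlorophyll-a is
  a lognormal seasonal curve peaking in summer (coastal central/southern
  Red Sea pattern).
* **Geosensors**: daily longitude = truth + N(0, 1°); tag SST = a linear
  meridional SST field (cooler north, mild seasonal cycle) at the true
  position + N(0, 0.5 °C); a synthetic western-coastline mask stands in
  for bathymetry and is labelled as synthetic.

What it does **not** emulate: tides and currents, plankton dynamics,
acoustic propagation physics (diel noise, thermoclines), behavioural
mechanism beyond mean reversion, tag loss, or receiver clock drift.
Passing tests therefore demonstrate that the pipeline recovers structure
*of the kind assumed*, not that it is robust to every failure mode of real
acoustic data.

## Problem sizes and determinism

The test suite runs the full pipeline on reduced windows (4–6 animals,
2–12 months) chosen so each stage is exercised end-to-end at interactive
run times; the GAMM recovery checks use ~50,000 animal-hours for the
single-fit shape test and 20 replicates of 10 × 120 days for the selection
study. All randomness flows from one seed per run with per-animal
substreams at fixed offsets; the suite asserts byte-identical outputs for
repeated seeded runs of simulate → filter → residency → model.

## Known limitations

* The speed filter's drop rule and the isolation window are conventions
  (configurable) — the source analysis does not specify them.
* GCV-based smoothing and conditional AIC are principled but not identical
  to REML-based selection; absolute AIC values and deviance-explained
  percentages are not comparable across implementations.
* Wald p-values for smooths are approximate; no autocorrelation-robust
  inference is attempted although hourly presence series are strongly
  autocorrelated.
* KUD contours are not clipped to the coastline.
* The geolocation observation models are simple Gaussians; real light and
  SST error distributions are heavier-tailed and seasonally varying.
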