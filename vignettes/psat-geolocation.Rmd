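---
title: "Grid-based HMM geolocation of PSAT-tagged fish: model, simulator and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based HMM geolocation of PSAT-tagged fish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psatHMM)
```

## The problem

Pop-up satellite archival tags (PSATs) attached to oceanic fish archive
depth, temperature and twilight-time estimates at 15-60 min resolution,
then detach — on a programmed date, or early when the fish has sat at
constant depth for several days — surface, and transmit a subset of the
archive plus an Argos pop-up position. None of this is a position record:
the migration route must be *inferred*. `psatHMM` implements the standard
state-space solution: the fish's daily grid cell is a hidden Markov state,
movement between days is a diffusion kernel, and each day's tag data define
a likelihood surface over the grid. The forward-backward recursion yields
daily posterior position distributions; routes, space-use surfaces and
behavioural summaries are derived from them.

## The model

**State space.** The ocean is discretised into cells (land excluded), in
two flavours: `latlon` (one state per lat/lon cell) and `distance`
(longitudinal spacing widened by $1/\cos\varphi$ so centers are roughly
equidistant in km). Both are provided because the two discretisations
induce slightly different random walks; `compare_tracks()` measures the
effect, which for basin-scale tracks is small relative to the posterior
uncertainty.

**Movement.** The daily transition weight is the one-day isotropic
diffusion solution,
$w(s \to d) \propto \exp\!\left(-\mathrm{dist}(s,d)^2 / 4D\right)$,
with great-circle distances in km and $D$ in km²/day, truncated to exactly
zero beyond $4\sqrt{2D}$ km and renormalised over ocean destinations. The
renormalisation reflects mass off coastlines rather than absorbing it —
fish do not beach. $D$ can be fixed or fitted by maximising the filter
log-likelihood with a golden-section search (1 % relative tolerance); a
flat likelihood (no movement information) returns the interval midpoint
with a warning rather than an arbitrary endpoint.

**Observations.** Each UTC day with data contributes

* *Light*: the twilight midpoint gives longitude at 15°/h from the
  local-noon offset; day length inverted through the solar hour-angle
  relation gives latitude. Within ±10 days of an equinox, or when the day
  length is within 10 min of 12 h, the inversion is degenerate and the
  latitude component is dropped entirely (`lat_usable = FALSE`) rather
  than down-weighted — an explicit, testable rule. Gaussian components
  with defaults $\sigma_{lon} = 0.5°$, $\sigma_{lat} = 1.5°$.
* *SST*: the mean of temperature samples shallower than 20 m, matched
  against the monthly SST climatology with $\sigma_{sst} = 0.7$ °C by
  default. Monthly fields are indexed by calendar month; no temporal
  interpolation (a climatology input is already a monthly average).
* *Maximum depth*: a hard feasibility indicator — water depth plus a 10 m
  tolerance (tag pressure error) must cover the day's maximum dive depth.

Missing components contribute uniformly. If a day's product is identically
zero (e.g. an SST match impossible everywhere), the day is flagged
degenerate and the filter uses the prediction alone; the event is counted
and reported, the track is not terminated. Day 0 is pinned to the release
site (point mass at the nearest ocean state) and the final day is
multiplied by a Gaussian anchor at the Argos pop-up position (default sd
10 km).

**Inference.** Filtering and smoothing run in linear space with per-day
renormalisation; the normalisers accumulate into the data log-likelihood.
Routes are reconstructed as the per-day *spherical* mean (dateline-safe)
of 1000 forward-filter backward-sampled (FFBS) trajectories. FFBS draws
from the joint posterior, so consecutive sampled positions are temporally
coherent — sampling each day's marginal independently would scatter
day-to-day steps far beyond anything the kernel allows.

## Space use and behaviour summaries

A fish's residency distribution (RD) is the mean of its daily smoothed
surfaces — a normalised space-use surface that carries positional
uncertainty. Population RDs combine fish whose migrations exceed 10 days
(strict inequality), weighting each fish equally by default so long
deployments do not dominate (`weight = "days"` pools fish-days instead;
both are exposed because either convention is defensible). Overlap between
populations is Bhattacharyya's affinity
$BA = \sum_c \sqrt{p_c\,q_c} \in [0, 1]$, computed on the full surfaces,
not on display contours.

Behavioural metrics: weekly mean great-circle distance from release
(7-day blocks from the release date) with an OLS slope over weeks 1-11
(the transit phase); the fraction of samples deeper than 10 m, with a
post-migration preset selecting samples strictly more than 77 days
(11 weeks) after release; and monthly five-number temperature summaries
per population using *all* samples (the temperature where the fish
resided, unlike the < 20 m SST filter).

All distances are haversine on a 6371.0 km sphere — at basin scale the
difference from an ellipsoidal geodesic is far below the positional
uncertainty.

## The simulator

Because real PSAT archives are proprietary, the package ships a generator
that reproduces the statistical structure the analysis assumes, and every
validation below runs on it.

* **Ocean**: SST decreases linearly polewards (default 0.4 °C per degree
  latitude, the basin-scale meridional gradient), oscillates seasonally as
  a cosine peaking in July (amplitude 3 °C), and carries a static spatial
  noise field (sd 1.2 °C) giving each cell a persistent thermal
  fingerprint of the kind mesoscale structure and frontal meanders provide
  in the subarctic Atlantic. A land strip with a linear shelf occupies the
  western edge. The default domain is 40° × 60° at 1°.
* **Fish**: a daily biased random walk — with probability `bias` (default
  0.8) the heading is the great-circle bearing to a distant foraging
  target, otherwise uniform; step length Gaussian (40 ± 8 km/day). Land
  steps are rejected and redrawn.
* **Tag**: per-sample surface/dive Bernoulli giving 80 % of samples
  shallower than 10 m, with log-normal dive depths; SST sensor noise
  0.5 °C; twilight times from the same mean-sun solar geometry the
  estimator inverts, with 10 min timing noise (PSAT onboard twilight
  estimates are coarse); i.i.d. per-sample dropout 0.31 reproducing the
  69 % mean data recovery; premature release when depth stays within 3 m
  over a trailing 4-5-day window; Argos pop-up noise sd 5 km.

Two generator choices deserve a note. Dives are independent per sample
rather than contiguous multi-hour events: the package's own consistency
checks require the surface fraction to behave binomially, and clustered
dives would not change any downstream quantity that the package computes
(daily max depth and the deep-sample fraction are insensitive to dive
contiguity), while they would make the surface-time check overdispersed.
And the solar model is a mean sun without the equation of time, used
identically in generation and inversion, so twilight midpoints map to
longitude without a date-dependent bias of up to ±4°; real-data
applications would add the equation-of-time correction to both sides,
which cancels in the same way.

What the simulator does *not* emulate: currents and fronts as dynamic
objects, burst-structured (rather than i.i.d.) transmission dropout,
depth-dependent temperature (every sample reports surface temperature
plus noise), prey fields, and behaviour-state switching. Passing the
validation suite therefore demonstrates that the inference machinery is
correct and well-calibrated *for data with this structure*; it does not
certify accuracy on real archives, whose light and SST error structure is
heavier-tailed.

## Validation design and problem sizes

The suite validates each stage against independent oracles at sizes chosen
to make the oracles exact:

* Filtering/smoothing marginals are compared with exhaustive all-paths
  enumeration on 200 random instances (up to 25 cells and 6 days, with
  the joint path count capped at $2\times10^5$ so the enumeration is a
  literal sum over every state sequence), agreeing to $10^{-10}$.
* FFBS day-marginals are checked against the smoothed surfaces in total
  variation (10,000 samples, ≤ 0.05).
* Route recovery runs 20 simulated 90-day deployments per SST-noise level
  {2.0, 1.0, 0.5} °C on the default 40° × 60° domain at 1°, with the
  estimator's error scales matched to the generator's sensor
  specifications ($\sigma_{lon} = 1.8°$, $\sigma_{lat} = 2.5°$,
  $\sigma_{sst}$ = the sensor sd) as a field calibration from known tag
  characteristics would set them. The median daily great-circle error of
  the mean-of-1000-tracks route must fall strictly as the sensor improves.
* Simulator self-consistency (surface time, data recovery) is tested
  within 3 binomial standard deviations at $n > 10^4$ samples, and the
  weekly-distance regression must recover a configured deterministic
  migration speed within 10 %.

## Numerical choices and edge cases

* Surfaces are renormalised every day; probability conservation is
  asserted at $10^{-9}$.
* Kernel truncation at 4 sd bounds cost and sparsifies the transition
  matrix; truncated and land mass are restored by row renormalisation.
* $D = 0$ yields the identity kernel (absorbing point masses), used as a
  degenerate-limit test.
* Anchors farther than max(3 sd, 3 cells) from any ocean state raise an
  error instead of silently snapping across land masses.
* Longitude convention $[-180°, 180°)$, cell-center registration, UTC
  days everywhere; spherical means make route averaging dateline-safe.
* Readers validate and reject; no input is silently repaired.

## Limitations

Single behavioural state and scalar $D$ (no transit/forage switching);
monthly climatology only; light positions are taken from tag-reported
twilights (no onboard light-curve processing); overlap is spatial only,
ignoring whether populations use shared areas in the same season. The
per-fish equal weighting of population RDs and the strict 10-day filter
are conventions; both are parameters.
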