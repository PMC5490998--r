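---
title: "Classifying surface-association behaviour from archival tag records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying surface-association behaviour from archival tag records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Juvenile bigeye and yellowfin tuna are caught in large numbers by
purse-seine fleets setting on floating objects (fish aggregating devices,
FADs), because aggregated fish sit high in the water column where the gear
can reach them. Archival tags record depth and ambient water temperature
every 10–300 s over months at liberty, and those records carry a
behavioural signature: long stretches in warm, shallow water with little
vertical movement look very different from the deep, cool, vertically
active behaviour these species otherwise favour, and from the diel pattern
of deep days and shallow nights. `surfassoc` turns that signature into a
per-fish, per-3-hours probability of *surface-association*, extracts
discrete surface-association events, and — when light-based geolocation
estimates exist — maps where the behaviour happened.

## Observation model and behavioural states

Raw samples are reduced to a bivariate series on a contiguous 3-hour grid
anchored at 00:00 UTC of the release day:

* **diving amplitude** — the sample standard deviation (n − 1 denominator)
  of depth within the bin, in metres; a proxy for vertical activity;
* **thermal habitat** — the mean ambient temperature within the bin, in °C.

A two-state hidden Markov model with bivariate-normal emissions is fitted
to each fish separately (`fit_hmm()`), so "shallow" and "deep" are defined
relative to each individual's own record; nothing is pooled across fish.
The state with the warmer mean thermal habitat is labelled *shallow*
("relatively warm and shallow"); if the two temperature means are within
0.1 °C the state with the smaller mean diving amplitude is taken instead,
and an exact tie on both criteria raises an error rather than guessing.
Emissions are fitted on untransformed diving amplitude by default; a
`log_depth_sd` switch applies `log1p` for records whose amplitude
distribution is strongly right-skewed.

Fitting is Baum–Welch EM. Bins that fail the coverage floor are kept on
the grid and *marginalized* (emission likelihood 1) rather than dropped,
the standard censored-HMM treatment — this keeps the grid contiguous for
the running mean below, which is why screening tolerates gaps up to 1 h
(shorter than one bin). Numerical choices:

* forward–backward uses per-step scaling constants (with log-space
  emission densities), which is algebraically equivalent to log-space
  recursions and does not underflow on chains of 10⁴+ bins (tested);
  backward variables are additionally renormalized per step so that even
  pathological models (e.g. an absorbing chain contradicted by its
  emissions) stay finite;
* covariance eigenvalues are floored at 1e-6 so zero-variance input
  (possible in synthetic data) cannot produce singular emissions;
* initialization 1 splits bins at the median thermal habitat (by rank, so
  ties cannot empty a group) and takes group moments; remaining restarts
  (`em_restarts`, default 3) perturb that start with a seeded RNG stream;
* convergence is a relative log-likelihood change below `em_tol`
  (default 1e-6) or `em_max_iter` (500); a restart is discarded as
  degenerate (state collapse) when a state's total responsibility falls
  below ~2 bins or the likelihood leaves the real line; all restarts
  degenerate is an error carrying the diagnostics;
* at least 64 valid bins (eight full windows) are required to fit at all.

The smoothed posterior P(shallow | whole record) from `smooth_posteriors()`
is the classification; we deliberately work with probabilities rather than
a Viterbi path, so downstream quantities inherit classification
uncertainty.

## Surface-association probability and events

The **surface-association probability** is the running mean of the
shallow-state posterior over `window_bins = 8` bins (24 h). Under diel
switching — 12 h shallow, 12 h deep — any 24-h window contains four of
each, so the running mean sits at exactly 0.5; sustained shallow occupancy
drives it to 1. This 0.5 anchor is the package's canonical worked example
and an acceptance check.

The window is *trailing* (ends at the current bin): an event is declared
only after a full day of accumulated shallow behaviour, matching the
definition of surface-association as 24 h of continuous shallow
classification. The first seven bins are therefore undefined. A
`centered` alignment is available for sensitivity analysis, since a figure
of the running mean cannot disambiguate the convention.

**Events** (`detect_events()`) are maximal runs of bins whose
surface-association probability *strictly* exceeds the threshold (default
0.75). Strict inequality matters: hard-classified series produce running
means exactly on 16ths, and 0.75 is attainable. The run length knob
`min_event_bins` defaults to 1 — "concurrent time-steps" is read as "one
or more" — and is exposed because the reading is genuinely open. The
0.75 default sits where the proportion of time classified as
surface-associative changes sharply across individuals;
`threshold_sweep()` reproduces that diagnostic over 0.01–0.99 in steps of
0.02, and its proportions are provably non-increasing in the threshold.

Per-fish metrics (`summarize_fish()`) include the mean probability at the
start, end and over the whole record, the proportion of (defined) bins in
events with and without release events, event counts and durations, and
events per month-at-liberty with `month_days = 30.4375` (the mean
Gregorian month; the choice is a convention, documented here because the
rate depends on it). A *release event* is any event starting within 24 h
of release. Records truncated by tag failure keep all whole-record
metrics but return `NA` for every recapture-window quantity (final 24 h,
final-week days), which are computed as seven trailing 24-h blocks ending
at recapture. Cohort-level outliers use the Tukey rule — duration above
Q3 + 1.5 IQR — with quartiles by linear interpolation
(`quantile(type = 7)`); the flags depend on the quantile convention, so it
is fixed and tested against a direct recomputation.

`dip_test()` assesses bimodality of summary distributions (e.g. the final
24-h probabilities) with Hartigan's dip statistic: the sup-norm distance
between the empirical CDF and the closest unimodal CDF (convex below the
mode, concave above — the greatest-convex-minorant / least-concave-
majorant geometry). The implementation bisects on the tube half-width and
decides feasibility with an exact chord-envelope sweep; it was validated
against an independent linear-programming formulation of the definition,
and frozen oracle values are asserted in the test suite. The p-value is
the fraction of `n_boot = 2000` uniform(0,1) bootstrap samples of equal
size with a dip at least as large — the standard calibration, stated
explicitly because the test's name alone does not fix it.

## Combining with geolocation

Light-based position estimates (three per day, consumed as input, never
estimated here) carry axis-aligned 95% confidence intervals. Each
estimate becomes an ellipse whose axes derive from the CI widths; the
default reads the width as the **full** axis (semi-axis = half-width),
with a `half` option, because the phrasing "axes equal to the confidence
interval" admits both readings. Each ellipse takes the
surface-association value of the temporally nearest defined bin (ties go
to the earlier bin; estimates more than half a bin outside the defined
span are dropped with a notice — typically the handful of estimates from
the first day, before the trailing window is defined).

Ellipses are rasterized on a 0.1° grid registered at multiples of the
cell size from the 0° meridian and equator, longitudes normalized to
[0, 360) so the grid is seamless across the antimeridian. A cell belongs
to an ellipse when its *centre* lies inside or on it (centre containment
gives an exact brute-force oracle; area weighting is out of scope), and an
ellipse smaller than a cell still claims its centre cell. Every claimed
cell inherits the ellipse's probability unchanged, and the map value is
the mean over all (ellipse, cell) observations touching a cell — equal
weight per observation regardless of fish, with counts retained so
low-support cells can be masked. Accumulation is streaming (sum, count)
and contractually identical to an all-at-once mean; the invariant
Σ(mean × count) = Σ attached probability is tested to float tolerance.

## The synthetic generator, and what passing tests mean

Real archival records of this kind are available only on request, so the
package ships a generator (`sim_scenario()`, `simulate_cohort()`) that
emulates the features the method relies on: diel switching on the 12 h/
12 h cycle, surface-association bouts that hold the shallow state for
days (log-normal durations, median 2 days, ~2.5 per month, bouts kept ≥2
days apart), a frequent multi-day post-release bout, thermal
stratification (shallow ≈ 28 °C, deep ≈ 18 °C — inside the warm band
reported for these species), optional data gaps and truncated records, and
bounded-random-walk tracks with latitudinal CI inflation typical of
equatorial light geolocation. Within each bin the drawn diving amplitude
and thermal habitat are imprinted *exactly* on the raw samples (depth
residuals are standardized, temperature jitter is mean-centred), so the
binned observations follow the scenario's state distributions by
construction and generator truth is exact at the bin level. Defaults were
chosen once to land cohort summaries at the scale reported for real
archives (roughly a fifth of time surface-associated, events of a
few days); they are emulation choices, not claims about any particular
data set.

The generator retains, per fish, the true state sequence, the planted bout
schedule, and the **induced event schedule**: the running mean of the true
0/1 state sequence, thresholded, computed inside the generator with
independent cumulative-sum arithmetic. Recovery tests compare pipeline
output against the induced schedule rather than raw bout boundaries,
because the trailing window delays threshold crossings by a diel-phase-
dependent 2–6 bins on each side — a property of the estimand's definition,
not an estimation error. Against the induced schedule, the fitted HMM
pipeline recovers event counts exactly and boundaries within ±1 bin on
10-fish cohorts (the ±1 arises only where the true running mean sits
exactly on the 0.75 threshold and posterior noise of ~1e-6 tips it).

What passing these tests does **not** show: real tags have sensor noise
and drift, depth-dependent temperature lags, behaviour that is neither
clean diel switching nor saturated association (thermocline-following
produces probabilities below 0.5), and state distributions that overlap
far more than the synthetic defaults. The generator validates the
machinery — estimator consistency, bookkeeping, conservation — not the
ecological interpretability of any particular threshold on any particular
archive.

## Problem sizes and reproducibility

The shipped test-suite and acceptance configurations use 10-fish cohorts
at a 300-s sampling interval with 31–90-day deployments, 2000-bin ×
20-replicate parameter-recovery studies, 1000-vector event-extraction and
100-ellipse rasterization oracle sweeps, and dip bootstrap tables of
500–2000 draws — sizes chosen to exercise every code path at full fidelity
while keeping a complete run in the low minutes on one core. All
randomness flows from a single integer seed: per-fish, per-restart and
bootstrap streams are derived deterministically from it, and re-running
the pipeline with the same inputs, configuration and seed produces
byte-identical outputs (tested). `scripts/acceptance.R --seed N --out f`
re-runs the whole analysis from scratch and writes the headline numbers
as JSON.

## Known limitations

* Two states only; no covariate-dependent transition probabilities,
  although residency near instrumented FADs would motivate them.
* The bin-grid anchor (midnight UTC of release day) is a convention; a
  different anchor shifts bin boundaries by up to 1.5 h and event
  boundaries by up to one bin. It is configurable for sensitivity checks.
* Surface-association is defined relative to each fish's own two-state
  decomposition; absolute depth/temperature envelopes of the states vary
  across individuals, and no attempt is made to harmonize them.
* Events cannot be attributed to actual floating objects — the tags do not
  observe them.
* The raster assumes independence of geolocation observations and plate
  carrée geometry; cells are not area-corrected with latitude.
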