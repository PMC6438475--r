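---
title: "Methods: onset-aligned analysis of LPS-induced cytokine cascades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: onset-aligned analysis of LPS-induced cytokine cascades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytocascade)
```

## The problem

Intraperitoneal (IP) endotoxin challenge provokes a cascade of plasma cytokine
elevations whose *order* is highly reproducible but whose *start time* varies
by tens of minutes between animals — and the variation is largely shared: an
animal whose first cytokine rises early tends to have its whole cascade
shifted early. Blood-volume limits force sparse sampling (here twelve 115-µL
draws: one 30 min before injection, one at injection, then every 30 min to
300 min). Averaging raw concentrations at fixed clock times therefore blurs
pulses into shallow, broadened humps and understates group effects.

`cytocascade` quantifies each animal on its own clock: fit a continuous curve
per series, locate the elevation starting point, align curves at that
landmark, and compare groups on the area under the aligned curves.

## The statistic chain

**Curve fitting.** Each series (≥ 4 samples, strictly increasing times) is
interpolated with a natural cubic spline and resampled on a 1-min grid
covering exactly the sampled span — never extrapolated. The smoothing
parameter defaults to 1, i.e. a pure interpolant: every measured value is
preserved. Values below zero between samples (interpolant undershoot near
sharp pulses) are clipped to zero on the resampled grid, because
concentrations are physical; the clip is recorded on the fitted object.
Setting `smoothing_parameter < 1` switches to a penalized smoothing spline
(roughness weight `(1 - p)/p`) for sensitivity analysis only.

**Baseline.** By default each curve is corrected by the mean of its fitted
values at pre-injection times (t < 0) before any peak or threshold logic.
Several cytokines have non-zero resting floors, and "elevation" is meaningful
only above them. `baseline_mode = "raw"` disables the correction; every
report carries the mode used.

**Peak.** Candidate peaks are interior local maxima of the corrected curve
with topographic prominence at least `prominence_fraction` (default 0.2) of
the curve's global corrected range; the *earliest* candidate is the peak
(first-peak rule). The prominence floor exists because an unfiltered
local-maximum rule fires on assay jitter. Two special cases:

* a curve still rising at its last sample (its last value is the running
  maximum) uses the last recorded concentration as the *effective peak* —
  late-rising cytokines have not always peaked inside the observation window;
* a series whose peak amplitude is not positive, or does not reach
  `min_elevation_ratio` × baseline (default 1, i.e. at least a doubling over
  the pre-injection level), is a *non-responder*: it is excluded from
  alignment and counted, reducing n. This is the operational form of
  "calculable elevation over the assay noise floor"; without it, baseline
  noise alone always yields some positive local maximum.

**Onset.** The starting point is the earliest grid time at which the
corrected curve reaches `onset_fraction` (default 0.05) of the peak amplitude
*and stays at or above that threshold until the peak*. On noise-free curves
this sustained-crossing rule coincides with the first touch; under noise it
ignores transient wiggles through the threshold. Onsets are reported at grid
resolution (ties toward earlier time). A curve already above threshold at its
first grid point is left-censored there and flagged rather than extrapolated.

**Alignment and effective AUC.** Each member curve is re-indexed to
t′ = t − t_onset; the set is truncated to the common duration
D = min(t_last − t_onset), the last aligned time at which every member is
still recorded; and each member is summarized by the trapezoidal integral of
its zero-clipped corrected curve on [0, D] (pg·min/mL). Alignment pools all
subgroups of a cytokine so their AUCs share one D and are comparable. AUCs of
series containing saturated readings are flagged as lower bounds.

**Group statistics.** Per-cell AUC vectors are screened by Tukey's fence
(type-7 quartiles, k = 1.5 by default; the screen is single-pass — repeated
application can remove more points because quartiles tighten). Subgroups are
compared by classical one-way ANOVA and post-hoc two-sided pooled
(Student's) t-tests — Welch's form is available but not the default, and no
multiple-testing correction is applied by default (a Benjamini–Hochberg
switch exists), matching the exploratory framing of this design. Effects are
reported as `100 · (mean − ref_mean)/ref_mean` with a direction call: cells
with |change| below `no_change_band` (default 15%) are "no change" regardless
of p-value, and significance is graded against α = 0.1, 0.05, 0.01.

## The synthetic cohort generator

No animal data are distributed, so the generator supplies cohorts with the
statistical structure the method assumes, plus full ground truth:

* **Onsets.** Animal i, cytokine c starts at
  `mu_c + delta_i + eps_ic`, with a shared shift `delta_i ~ N(0, 15 min)`
  common to the animal's whole cascade and residual jitter sized so the
  marginal SD equals each cytokine's specified `sd_onset` exactly. The shared
  term dominates, reproducing the observation that a whole cascade shifts
  together; 15 min is a choice — the source data report no variance
  decomposition — and the split is configurable.
* **Pulses.** A piecewise gamma hump: rising limb `u^k e^{k(1-u)}` with
  k = 5 (a smooth, sigmoid-like foot), falling limb the same family with
  `k = rise_tau/decay_tau`, C1 at the peak, so the late decay is exponential
  with constant `decay_tau`. The drawn onset is placed at the pulse's
  *5%-of-peak crossing* (the latent pulse start is back-shifted by the
  analytic crossing lag), because the published starting points are defined
  by the 5% rule — the generator parameter lives on the scale the pipeline
  estimates, which is what makes parameter-recovery tests meaningful.
  Rise times default to 75–90 min and decays to twice that, consistent with
  the published average IP profiles. The foot smoothness matters: pulse feet
  much shorter than the 30-min sampling interval cannot be reconstructed by
  any interpolant, and the 5% crossing of the fitted curve is then
  systematically early. With these defaults the pipeline's mean-onset bias is
  ≤ ~1.5 min per cytokine, within Monte-Carlo error of the drawn means.
* **Default panel.** Seven responsive cytokines parameterized by their
  published IP starting-point means and SDs (IL-10 49.2 ± 18.6 through IFN-γ
  186.6 ± 25.2 min), responder probabilities 29/44, 41/44 and 26/44 for
  IL-17F, IL-6 and IL-22, amplitudes and floors order-of-magnitude realistic
  for rat plasma (IL-6 in the tens of ng/mL with a finite upper
  quantification limit, so occasional saturation occurs). An IV variant
  (earlier, tighter IL-10/TNF-α onsets) supports route-contrast figures.
* **Noise and censoring.** Multiplicative lognormal measurement noise
  (default CV 10% for experimental cohorts); values below half the baseline
  floor are floor-censored (`below_floor`), values above the saturation limit
  clipped (`saturated`). One master seed drives everything; the latent truth
  consumes a fixed number of draws regardless of the sampling schedule, so
  sparse and dense cohorts from one spec share ground truth.

What the generator does *not* emulate: pharmacokinetics (absorption,
clearance mechanisms), inter-cytokine amplitude correlations beyond the
shared time shift, drifting baselines, or heavy-tailed assay artifacts.
Passing tests therefore certify the statistic chain against data with the
*assumed* structure, not the full messiness of plasma immunoassays.

## The offset-subsampling validation

To certify that sparse 30-min sampling supports the chain, densely sampled
series (10-min steps) are split into staggered 30-min subsets — offsets 50,
60 and 70 min reproduce the three-curve scheme used to validate the original
method — and the full fit → onset → AUC chain runs on each subset. Per
series the report gives the spread (max − min) and SD of onsets across
subsets and the relative spread and relative SD of effective AUCs (each
subset integrated from its own onset over the series' common duration). The
harness's certification runs use a 5% measurement CV, a typical intra-assay
CV for bead-based multiplex immunoassays — subset disagreement is a
repeatability question, so the intra-assay figure is the relevant one.

Two structural facts about this harness are worth knowing. First, even
noise-free, the three subsets disagree by ~3 min in onset on 30-min grids:
each subset samples the pulse foot at a different phase, and the interpolant's
5% crossing moves within about a [−3, +1] min window around truth. The
max − min across three subsets therefore sits near 3 min before any noise is
added, while the SD across subsets stays under 2 min. Second, AUC spread is
noise-dominated: three disjoint 6–7-point subsets with 5% per-point CV differ
by ~3–4% in max − min (≈2% SD). Both metrics are always reported side by
side; "spread" claims should name which one they mean.

## Numerical and design choices

* Quartiles use R's default linear-interpolation convention (type 7); the
  original convention is unstated.
* Onset grid rounding is upward (first grid time at or above threshold), ties
  toward earlier time; resampling is 1 min by default.
* The grid always contains the first and last sample exactly; a non-multiple
  span shortens the final step.
* Whether the original analysis baseline-corrected before applying the 5%
  rule is unstated; correction is this package's default, raw mode is one
  switch away, and every output names the mode.
* Time-shift equivariance of the cascade statistics is exact in raw mode;
  with baseline correction the pre-injection window is pinned at t < 0 by the
  time convention, so only shifts that leave the window's content unchanged
  are exactly neutral.
* Degenerate inputs: < 4 points or duplicate times are rejected at fit time;
  flat series raise a typed no-elevation condition that bulk operations catch
  and count; zero-variance t-tests return t = 0, p = 1 when means agree.

## Problem sizes used in the test suite

Unit and property tests run on handfuls of series. The end-to-end
distributional checks use: 24 dense TNF-α-like pulses for the offset harness;
100 replicate cohorts of 44 animals × 7 cytokines for onset recovery and
cascade-order checks; 1,000 small-sample replicates for t-test type-I
calibration. These sizes put Monte-Carlo error well inside the tolerances
being asserted while keeping the default suite in the minutes range.

## Known limitations

* The 5% rule needs a clean pre-onset floor; curves already elevated at the
  first draw are left-censored, not extrapolated.
* Effective peaks understate true amplitudes for late-rising cytokines, which
  slightly advances their estimated onsets; the effect is visible for the
  latest cytokine in the default panel (~1–2 min at n = 44).
* With 30-min sampling, single-subset onset estimates carry a few minutes of
  phase-dependent reconstruction error; cohort means are far more stable.
* The effect matrix reproduces the direction/significance *structure* of a
  published stimulation-effect table; cell-for-cell agreement with any
  specific animal dataset is out of reach without that dataset.
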