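---
title: "Hypotension burden metrics and trial simulation: methods"
author: "hypoburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hypotension burden metrics and trial simulation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoburden)
```

## The burden model

A patient's intraoperative MAP stream is modelled as a piecewise-linear
function of time through the monitor's beat-averaged samples (nominally
every 20 s). All burden quantities are defined on that continuous trace,
with the hypotension threshold θ (default 65 mmHg, strict: MAP exactly at
θ is *not* hypotension):

* a **hypotensive episode** is a maximal interval with MAP(t) < θ;
  crossing times are computed exactly by linear interpolation between
  samples, which makes episode boundaries stable under grid refinement —
  resampling a series to a finer grid and re-summarizing returns the same
  counts, times and areas;
* **absolute time** in hypotension is the Lebesgue measure of
  {t : MAP(t) < θ}, and **relative time** divides by the surgical
  duration;
* the **area under the threshold** (AUT) is ∫ max(0, θ − MAP(t)) dt in
  mmHg·min;
* the **time-weighted average** (TWA) of hypotension is AUT divided by
  the surgical duration, in mmHg.

Two AUT conventions circulate in the clinical literature: the true
integral, and the shorthand (θ − nadir) × total time below θ. They agree
only when every excursion sits at a constant depth (the textbook
five-episodes-of-1-min example gives 25 mmHg·min and TWA 0.25 mmHg under
both). We implement both; the default is the trapezoid integral because
it is the quantity the time-weighted-average construct actually averages,
and because the shorthand is an upper bound (depth ≤ maximum depth
pointwise). The choice is a `method` flag on `area_under_threshold()` and
`hypo_summary()`.

Episode debouncing — discarding episodes shorter than `min_duration`,
then merging episodes separated by less than `merge_gap` — defaults to
off (both 0 s): clinical definitions rarely state a debouncing rule, so
the undebounced counts are the least surprising default, and total
episode time then equals total time below threshold exactly.

## Trial statistics

The two-arm comparisons use the estimators standard in small
perioperative trials, written out in full rather than wrapped:

* **Mann-Whitney U**: midrank U statistic; the exact two-sided p-value
  enumerates the null distribution of U through the classical count
  recursion f(u; m, n) = f(u − n; m − 1, n) + f(u; m, n − 1) (used
  automatically when n·m ≤ 400 and the pooled data are tie-free), and
  the normal approximation applies the tie correction to the variance
  plus a 0.5 continuity correction. At 20 patients per arm the two paths
  agree to well within 0.02.
* **Hodges-Lehmann**: the location difference is the median of all n·m
  pairwise differences, oriented intervention − control so that a
  benefit of proactive management is negative. The confidence interval
  takes order statistics of the sorted pairwise differences at ranks
  from the Mann-Whitney null distribution; when the exact rank is not
  achievable the interval widens to the nearest achievable rank
  (conservative), and the approximate rank uses the floor for the same
  reason.
* **Spearman** correlations are Pearson correlations of midranks with
  the t-approximation p-value; **chi-square** is Pearson's statistic
  without continuity correction; **normality** is checked by the
  one-sample Kolmogorov-Smirnov distance to a normal with plugged-in
  sample mean and SD. Because the parameters are estimated, the
  classical KS null is wrong for this statistic, so the p-value is
  simulated from the fitted null under a fixed internal seed (default
  2000 replicates) without disturbing the caller's RNG stream.

Quartiles use the type-7 (linear interpolation) rule and the IQR is
reported as the single width Q3 − Q1, matching the `median (IQR)`
presentation of clinical tables. No multiple-testing adjustment is
applied — each p-value is marginal, mirroring common pilot-trial
reporting; this is a deliberate limitation, not an oversight.

## Biomarker analysis

Panels of eight analytes are drawn at T0 (pre-induction) and T2 (end of
surgery). Correlations between biomarkers and burden default to the
T2 − T0 **deltas** rather than raw T2 values: the delta isolates the
intraoperative change from between-patient baseline variation, which is
the association of scientific interest. Raw-T2 correlations are available
via `value_mode = "post"`; this is an interpretive choice, documented
here because published correlation tables rarely state which was used.
Cells with fewer than three complete pairs are reported unavailable
rather than imputed.

## The decision rule engine

The proactive policy fires only above the alert threshold (HPI > 85%);
after an artifact check it branches on preload responsiveness
(SVV > 13% → fluid), arterial tone (Eadyn < 0.8 → vasopressor), then
contractility (dP/dt max < 480 mmHg/s → inotrope), else observation. The
reactive policy applies the same branch logic gated on established
hypotension (MAP < 65 mmHg) instead of the alert. The alert and MAP
gates are the study-defined constants; the three branch thresholds are
conventions from standard hemodynamic practice — published decision
algorithms of this family do not pin them numerically — so every
threshold lives in `rule_config()` and is serialized with the simulation
configuration. The default branches are mutually exclusive by
construction; a "combination" action would only arise from a user
configuration that fires several branches, which the engine does not do
by default.

## The trial generator

`simulate_surgery()` composes three ingredients, chosen so that episode
count, depth and duration are independently tunable:

* **background**: an Ornstein-Uhlenbeck (exact AR(1) discretization)
  process around a baseline of 73 mmHg, stationary SD 2 mmHg, reversion
  time constant 2 min, sampled every 20 s. The small SD reflects an
  anesthetized, managed patient: background noise alone almost never
  produces hypotension (about 1.5% of surgeries), so the incidence is
  event-driven;
* **stress events**: a Poisson process (default 0.585 events/h), each a
  triangular MAP depression with gamma-distributed depth (shape 3, mean
  12 mmHg) and lognormal full duration (median 10 min, σ = 0.5). Events
  deep enough to establish hypotension trigger the reactive policy,
  which halves the recovery limb (`reactive_attenuation` = 0.5) —
  treatment shortens but does not avert an established episode;
* **alerting** (intervention arm only): each event is alerted with
  probability 0.85 at 300 s before its nadir — sensitivities and lead
  times in that range are what published early-warning evaluations
  report — and an alerted event is averted outright with probability
  `treatment_efficacy` = 0.804, with the proactive policy call recorded
  in the event log.

Surgery durations are lognormal with medians 207 (intervention) and 237
(control) minutes; the log-SDs (0.228, 0.374) are back-computed from the
reported interquartile ranges of 64 and 121 min via
σ = asinh(IQR / (2·median)) / z₀.₇₅.

The `event_rate` and `treatment_efficacy` defaults were fixed once by a
bisection against the two incidence targets — 80% of control patients
and 38% of intervention patients with at least one episode — and then
verified on independent seeds (80.3% / 38.0% at 10,000 surgeries per
arm). They are part of the generator's definition, not tuning knobs.

Biomarker responses are generated as `delta = drift + slope × metric +
noise`, with S100B keyed to episode count (slope 0.252 pg/mL per
episode) and NGAL keyed to TWA (slope 1.55 ng/mL per mmHg); those two
slopes were calibrated once so the pooled Spearman correlations at large
n center on 0.584 and 0.316. NSE carries a positive and GSH a negative
burden slope, so the intervention arm shows lower NSE rises and better
GSH preservation purely through its lower burden; the remaining analytes
(HIF-1α, acetyl-CoA, troponin, LOOH) have zero slope, encoding
burden-independence. Negative generated concentrations are truncated at
zero with a warning.

Randomization uses permuted blocks of 4 and 6 (1:1 within block); the
block-size sequence is drawn by rejection until it sums exactly to the
trial size, so final arm counts are always equal and no assignment
prefix is imbalanced by more than half the largest block. When the
configured blocks cannot compose the requested size (e.g. one patient
per arm), `simulate_trial()` falls back to a single balanced block so
degenerate configurations still run; arm-level reports then flag
insufficient data instead of crashing.

Reproducibility: one master seed; per-patient (and per-purpose)
substreams are derived as `(master·48271 + index·16807 + stream·69621)
mod (2^31 − 19) + 1`, so patient i can be regenerated in isolation and
two runs with the same `(config, seed)` are bit-identical. All stochastic
helpers save and restore the caller's RNG state.

## Power for a binary incidence endpoint

`power_simulation()` draws binomial incidences per arm and applies a
two-sided two-proportion z-test with the *pooled* standard error under
the null (the chi-square-equivalent form). Sample-size statements of
"80% power for 80% vs 38% at 20 per group" are reproduced by this pooled
calculation (analytic 0.794; exact enumeration 0.791), whereas the
unpooled z-test gives 0.850 at the same design — which is why pooled is
the default. A Welch t-test on the 0/1 encoding is available via
`test = "t_test"` and agrees with the pooled test to within Monte-Carlo
error at this design.

## What the generator does and does not emulate

The generator reproduces the statistical structure the analysis consumes:
two balanced arms, realistic surgery durations, an 80%/38% incidence
contrast, burden distributions with many zero-burden intervention
patients, and biomarker-burden rank correlations at the calibrated
magnitudes. It does **not** attempt cardiac-output physiology, drug
pharmacokinetics, or the burden medians seen in real cohorts (its median
control TWA sits below the 0.1-0.4 mmHg range typical of real series,
because incidence and severity cannot be matched simultaneously with a
single event process calibrated to incidence). Passing tests therefore
demonstrate the correctness of the metrics and statistics and the
internal consistency of the simulated trial — not that real surgical
data would show these effect sizes. Note one structural consequence of
the 38% incidence target: the median intervention-arm episode count is
0, which is more extreme than real intervention arms, where the median
patient still experiences a few episodes.

## Numerical conventions and edge cases

* MAP exactly equal to the threshold is never hypotension; a series
  touching 65 mmHg from above has zero burden.
* Episodes are detected on the refined trace whose breakpoints include
  every interpolated crossing; a segment's side is judged at its
  midpoint, avoiding sign ambiguities at touch points.
* `resample_to_grid` preserves both endpoints (the last grid point is the
  final timestamp even when the span is not a multiple of the step) and
  never extrapolates.
* Ingest drops rows with non-finite MAP and reports the count; it never
  imputes. Gaps are handled by the same linear interpolation as
  everything else.
* The exact Mann-Whitney path refuses tied data rather than silently
  approximating; `auto` mode makes the switch explicit in the result.
* Exactness checks in the test-suite compare the trapezoid integral
  against an independent Riemann oracle with numerically located
  crossings (agreement to 1e-9 relative), Mann-Whitney p-values against
  full enumeration up to 8 + 8 per arm, and Hodges-Lehmann intervals
  against the established reference implementation on the exact path.

## Problem sizes used in the checks

The packaged checks run at sizes chosen to keep the whole suite fast on a
laptop while leaving Monte-Carlo error well inside the asserted
tolerances: 10,000 surgeries per arm for the incidence calibration,
20,000 replicates for power, 10,000 null trials for the type-I error of
the arm comparison (observed within 5% ± 1%), 200 trials for the
direction-of-effect check, and pooled cohorts of 500 patients (plus 25
trial-sized replicates) for correlation recovery.

## Known limitations

* The burden metrics trust the monitor's artifact handling; no signal
  quality model is included.
* The generator's event shapes (triangular pulses, gamma depths) are
  conventions: published summaries do not constrain the within-episode
  MAP profile.
* The biomarker model is linear in one burden metric per analyte with
  Gaussian noise; real panels are right-skewed with assay floors that we
  do not model beyond truncation at zero.
* No multiplicity control across the eight analytes or four outcomes.
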