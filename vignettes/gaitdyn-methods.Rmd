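---
title: "Methods: stride variability, local dynamic stability, and the cohort inference layer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stride variability, local dynamic stability, and the cohort inference layer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitdyn)
```

# Scope

`gaitdyn` implements the analysis chain of a two-group (young vs. older
adults), three-condition (overground, treadmill, visually cued treadmill)
repeated-measures gait study: stride-to-stride variability as the percent
coefficient of variation (%CV) of stride time and stride length; local
dynamic stability as the short-term local divergence exponent (LDE) of
tri-axial lumbar acceleration; generation of the visually cued stepping
stimulus; and the 2 × 3 mixed-ANOVA inference layer. A seeded synthetic-data
module makes every stage testable without any recorded data.

# Stride variability

For a stride-parameter series the package reports
\[
\%CV = \frac{\text{sample SD}}{\text{sample mean}} \times 100,
\]
with the \(n-1\) SD denominator. Trials are bilateral: `bilateral_cv()`
computes the %CV per leg and averages the two (`mode = "legmean"`). Field
conventions differ on whether per-leg statistics are combined before or
after forming the ratio, and the difference is small but not zero; the
alternative order (`mode = "pooled"`: mean of the per-leg SDs over the mean
of the per-leg means) is therefore exposed and tested too. %CV is invariant
to stride order and to rescaling of the parameter, and both properties are
asserted in the test suite.

# The local divergence exponent

The estimator follows the established divergence (Rosenstein-type)
construction for trunk accelerometry:

1. **Bout structure.** Trials are cut into 11 non-overlapping bouts of 8
   strides (`plan_bouts()`), taken earliest-first. A bout spans
   `strides + 1` consecutive stride events with shared boundaries, so 11 × 8
   strides require 89 events. Placement at the start of the trial is a
   determinism choice; the estimator is invariant to trailing data.
2. **Time normalization.** Each stride is linearly resampled to 100 samples
   (`time_normalize()`), so normalized time is measured in strides and an
   8-stride bout is an 800 × 3 array. The 100-samples-per-stride reading is
   the one consistent with a 25-sample delay being a quarter gait cycle; a
   100-samples-per-bout reading would be incompatible with 8-stride bouts.
3. **State space.** `delay_embed()` forms a 9-dimensional state from the
   three axes and two delayed copies each (delay 25 samples = 1/4 cycle):
   750 states per bout.
4. **Divergence curve.** For each state the nearest Euclidean neighbour
   outside a Theiler window is found (ties to the smallest index, making
   the estimator deterministic), and the mean log distance between the pair
   is followed forward (`divergence_curve()`). The Theiler window defaults
   to one mean period — 100 normalized samples — which for
   stride-normalized data excludes same-cycle matches.
5. **Slope.** The short-term exponent is the OLS slope of the mean log
   divergence over 0–0.5 stride, rescaled to nats/stride
   (`fit_short_term_lde()`). The 0–0.5-stride window is the dominant
   short-term convention in the trunk-accelerometry literature; 0–1 stride
   is available via `window = 100`. Per-bout curves are averaged pointwise
   and a single slope fitted (`lde_for_trial()`); fitting per bout and
   averaging the slopes is exposed as `aggregate = "per_bout"`. Because OLS
   is linear in the curve, the two modes coincide exactly when bouts are
   identical, which is asserted in the tests.

Distances are Euclidean in the raw 9-D space with no per-channel
normalization (all three channels share units); a global rescaling of the
signal shifts the log-divergence curve additively and leaves the slope
unchanged, and this invariance is asserted numerically. A constant signal
makes all states identical and is flagged as degenerate rather than
propagating `-Inf`; isolated zero distances are floored at 1e-12 before the
log.

## Validation against an independent oracle

The estimator's correctness is checked on systems whose largest Lyapunov
exponent is known independently:

- `benettin_lyapunov()` integrates a system together with its linearized
  tangent dynamics (fixed-step RK4, step 1 ms), renormalizing the tangent
  vector every step — the classical tangent-space method, algorithmically
  unrelated to the divergence path. On the Lorenz system
  (σ = 10, ρ = 28, β = 8/3) it returns ≈ 0.902 nats/s, matching the
  literature value of about 0.906.
- `lyapunov_rosenstein()` applies the package's own divergence estimator to
  a sampled Lorenz trajectory (100 Hz, 10 s transient discarded). For
  physical-time signals the delay and fit window default to a quarter of
  the signal's spectral mean period and the Theiler window to one mean
  period. The quarter-period fit window keeps the fit inside the initial
  exponential-divergence regime: longer windows run into the saturation
  shoulder where the curve flattens and the slope becomes biased by how
  much of the shoulder is included. Across seeds the divergence estimate
  falls within about ±15% of the tangent-space value; the acceptance suite
  requires ±20%.
- Three phase-shifted sinusoids (`reference_system("sine")`) and a
  noise-free periodic gait signal bound the non-chaotic limit: the fitted
  slope must not exceed 0.05 nats/stride (observed: ≈ 1e-14).
- The C++ nearest-neighbour kernel is compared against an exhaustive
  R-side distance-matrix search on 300-state problems.

# Synthetic data

The generator emulates the study's structure, not any participant's actual
values (per-cell means are not published; only the ordering patterns are).

**Stride-parameter cohorts.** `cohort_spec()` fixes 25 participants per
group walking 3 minutes per condition. Per (group, condition) cell it
carries mean stride time and length, and a target within-participant %CV.
Participant heterogeneity has three parts: a Gaussian intercept on each
measure's mean (`sd_between`), a mean-one lognormal factor on the
within-participant SDs (`cv_dispersion = 0.2`) shared across conditions —
this is what gives the %CV outcomes their repeated-measures correlation —
and, for the LDE outcome, a per-condition Gaussian residual. Strides are
i.i.d. Gaussian within a trial by default: the study-level statistics the
package reproduces (%CV and cell means) are insensitive to stride-order
autocorrelation, and no autocorrelation structure is claimed by the design;
an AR(1) option (`ar1`) exists for sensitivity analyses. The within-SD
needed to hit a cell's %CV target varies by cell — a single per-measure SD
cannot produce condition-dependent %CV orderings, which is why the spec
stores per-cell %CV targets rather than one SD per measure.

The default cell values are chosen once to reproduce the qualitative
orderings reported for this paradigm — variability and LDE highest under
visual cues in both groups, older above young on both treadmill conditions,
near-identical %CV overground (the overground cells are set exactly equal
between groups, since the study reports no overground group difference for
the CV measures), and LDE elevated in older adults in all conditions. They
are laboratory-plausible magnitudes (stride time ≈ 1.05–1.09 s, stride
length ≈ 1.30–1.46 m, %CV ≈ 1.9–4.4, LDE ≈ 1.1–1.8 nats/stride), not
estimates read off any figure.

**Acceleration signals.** `simulate_lumbar_accel()` repeats a fixed
low-order harmonic base waveform per stride (coefficients documented in
`base_gait_waveform()`), time-warped to each stride's duration, amplitude-
scaled per stride, plus white sensor noise; the vertical channel peaks
exactly at the stride origin, so ground-truth events align with the
waveform's phase origin by construction. What this deliberately does not
model: turning strides (the overground walkway's turns), double-support
asymmetries, drift, or any biomechanically detailed dynamics. Passing tests
therefore demonstrate the *estimator pipeline* (detection → bouts →
embedding → divergence) under controlled instability, not fidelity to any
specific participant's signal.

**Reference systems.** The Lorenz equations are integrated with fixed-step
RK4 (step 1 ms, 10 s transient discard, 300 s default duration, sampled at
100 Hz); seeds jitter the initial condition so replicates sample different
stretches of the attractor.

# Event detection and problem sizes

`detect_strides()` band-pass filters the vertical axis (Butterworth order
2, zero-phase, 0.25–3.5 × the expected stride frequency) and picks peaks at
least 0.6 expected stride times apart and above half the filtered SD. On
synthetic signals with realistic noise it recovers ≥ 99% of ground-truth
events within ±3 samples; the tests require ≥ 95%. A flat signal yields an
empty event list (a valid result), while a signal shorter than two strides
is an error.

Simulation sizes used by the tests and the acceptance script are chosen to
keep full runs in the range of a few minutes on one core while leaving
Monte-Carlo error well inside the asserted tolerances: 500 replicates at
n = 10/group for the type-I calibration, 20 replicates for the noise
monotonicity and bout-robustness studies, 150 s of Lorenz trajectory for
the chaotic validation, and 9 replicate cohorts for the pattern check.

# The inference layer

`mixed_anova()` performs the classical SS decomposition for one
between-subjects and one within-subjects factor with subjects nested in
groups. Design choices:

- **Balanced designs only.** The emulated study is balanced (25/25), and
  classical SS types coincide only then; unbalanced input is an explicit
  error rather than a silently type-dependent answer.
- **Sphericity.** Greenhouse-Geisser ε is computed from the pooled
  within-group covariance of the conditions (bounds 1/(k−1) ≤ ε ≤ 1
  enforced), with Mauchly's test on the same matrix. The corrected p is
  reported when Mauchly p < 0.05 (`gg = "auto"`), mirroring conditional
  practice; `"always"`/`"never"` override. Both routes are cross-checked
  against `car::Anova`'s univariate output in the suite.
- **Effect sizes.** Partial η² is computed both as SS\_effect/(SS\_effect +
  SS\_error) and as F·df₁/(F·df₁ + df₂); the two are asserted equal to
  1e-12 on every fitted table, and the second form is what lets the nine
  published F statistics be converted to their published η² values exactly
  (three decimals) without any raw data.
- **Post hocs.** Condition contrasts are paired t-tests pooled across
  groups (one Holm family of three); group-specific families are available
  via `by_group = TRUE` since study figures often annotate group-specific
  condition differences. Simple main effects of group within condition are
  pooled-variance two-sample t-tests, Holm-adjusted as a family of three.
  All tests are two-sided at α = 0.05.
- **Power.** `posthoc_power()` uses the noncentral-F repeated-measures
  convention with noncentrality inflated by m/(1−ρ) for within and
  interaction effects. The repeated-measures correlation ρ is not something
  a published η² determines, so power statements are assumption-dependent;
  with the conventional ρ = 0.5 the smallest reported interaction
  (η²ₚ = 0.086, N = 50) gives power > 0.99, consistent with a "well above
  80%" claim under any moderate ρ.

Under the null cohort generator the rejection rate of each effect at
α = 0.05 stays inside the 95% binomial interval over 500 replicates —
the conditional GG policy does not distort type-I error under sphericity.

# Visual cues

`generate_cue_sequence()` renders the stimulus schedule: one foot-sized
rectangle per step, arrival period `step_length / belt_speed`, sides
alternating, lateral offsets ±step_width/2, all cues translating backward
at belt speed (coordinates: walking axis positive forward, origin at the
treadmill front edge — stated explicitly because no standard frame exists).
Rectangles are the participant's foot dimensions plus a 20% margin;
shoe-size-to-foot-dimension mapping is left to the caller since reported
conventions vary by region and vendor. `validate_cue_sequence()` re-derives
alternation, spacing, speed and symmetry from a schedule and counts
violations; the round trip from the generator is violation-free, and the
tests plant single faults to confirm the counts.

# Known limitations

- The synthetic cohort reproduces the published significance *pattern*, not
  the published F values: those depend on the study's actual participant
  values, which the package does not bundle. `run_study(measures = ...)`
  accepts such a per-participant table (long, or wide
  `<measure>.<condition>` columns) and then reproduces its statistics
  exactly.
- The 11-vs-15-bout equivalence is assessed on synthetic participants; with
  16 participants the paired-t Cohen's d has sampling SD ≈ 0.25 even when
  the two bout counts are exactly equivalent, so single replicates
  exceeding |d| = 0.3 are expected about a quarter of the time and only the
  replicate ensemble is informative.
- Stride-length "measurement" is generated, not estimated from kinematics;
  detection is peak-based on the vertical axis and is not designed for
  pathological or turning gait (an explicit event mask can be passed to
  `plan_bouts()` callers by pre-filtering events).
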