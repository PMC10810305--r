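---
title: "Methods: simulating and analyzing myoelectric ankle-exoskeleton adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing myoelectric ankle-exoskeleton adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomyo)
```

## The problem

Ankle exoskeletons under proportional myoelectric control command their
actuator continuously from the user's own plantar-flexor muscle activity:
the soleus surface EMG is filtered into a low-frequency envelope, scaled by
a subject-specific gain into a motor current, and transmitted into a
plantarflexion torque. The scientific questions around such devices concern
*adaptation*: does triceps surae activity decrease as users practice with
assistance, how much of the total ankle moment, power and positive work
does the device contribute, and how do the device's own sensors disagree
with laboratory motion capture?

`exomyo` implements both sides of that study as a tested pipeline:

* a **synthetic generator** producing multi-subject, multi-condition
  walking recordings (raw EMG, joint angles/moments, vertical GRF,
  exoskeleton-reported angle) with *known* ground truth;
* the **controller** chain as deployed on such devices;
* the **analysis**: stride segmentation, 101-point gait-cycle
  normalization, EMG normalization and phase-restricted RMS,
  exoskeleton/biological ankle decomposition, and scalar plus curve-level
  statistics.

Because no human recordings accompany the study design, the generator *is*
the data source; every analysis claim in the package is tested either
against closed forms, against independent oracles, or as parameter
recovery against the generator's ground truth.

## The protocol being emulated

A single 50-minute treadmill session of four conditions: 5 min walking in
the boots alone (*BootsOnly*), 5 min with exoskeletons attached but
unpowered (*Unpowered*, during which the controller is calibrated), 30 min
powered (*Powered*), and 10 min with the device switched off again
(*Deadaptation*). Six analysis windows of 30 strides each are taken: the
last 30 strides of BootsOnly, Unpowered, Powered (*PoweredEnd*) and
Deadaptation (*D2*), and the first 30 strides of Powered (*PoweredStart*)
and Deadaptation (*D1*).

## The controller

The control envelope is a causal chain: 2nd-order Butterworth high-pass at
50 Hz, full-wave rectification, 2nd-order Butterworth low-pass at 8 Hz
(`preprocess_emg()`). Causality matters: the physical device runs in real
time, so the package's control chain is strictly forward-only with
zero initial conditions, and a test asserts that truncating the input
leaves the preceding output unchanged. For *analysis* the package uses the
zero-phase variant (`analysis_envelope()`, forward–backward filtering), so
cycle-normalized envelopes are not phase-lagged against the mechanics;
this distinction (causal control, zero-phase analysis) is the package's
choice where practice is silent.

Calibration (`calibrate()`) maps the maximum envelope observed during
unpowered walking to the q-axis current cap:
`gain = i_max / max(envelope)`, with `i_max = 7.6` A (the 20 A
line-to-line equivalent is stored as an informational constant only — the
vendor's conversion is not computable from published information). The
deadband threshold is 5% of the calibration maximum; the device is then
transparent whenever the muscle is quiet. The threshold *definition* is the
package's own (field practice varies and is rarely reported); 5% keeps the
device silent through late swing at the generator's noise floor.
Current maps to torque through a transmission ratio, by default a constant
2 Nm/A (so a saturated 7.6 A commands 15.2 Nm, inside the 7–17 Nm
day-one range such devices produce), with a tabulated
ratio-versus-angle hook for variable transmissions; the commanded torque
is clipped at zero because the device assists plantarflexion only. The
first 2 s of any calibration window are discarded (filter start-up).

## The synthetic generator

Within-cycle shapes are smooth periodic templates of cycle phase (heel
contact at 0%): sagittal ankle/knee/hip angles and moments, and an
M-shaped vertical GRF that is exactly zero in swing (stance occupies 60%
of the cycle in the generator; downstream analysis still uses the
event detector rather than assuming 60%). EMG envelopes are sums of
Gaussian bursts per muscle; raw EMG is that envelope (plus a 5 µV noise
floor) modulating a band-limited (20–450 Hz) zero-mean unit-RMS Gaussian
carrier — the standard surrogate that preserves envelope statistics
without modelling motor-unit physiology. Stride durations are lognormal
around the 0.9 strides/s cadence (CV 3%); cadence, EMG gain, mechanical
amplitudes and adaptation magnitude all carry between-subject lognormal or
Gaussian spread.

Adaptation is a single-parameter exponential per muscle: the envelope is
multiplied by `1 + change * (1 - exp(-t / tau))` with `t` the powered
practice time. Steady-state changes default to the studied regime
(soleus −12%, medial gastrocnemius −5%, lateral gastrocnemius −17%,
tibialis anterior +9%), and `tau = 6` min puts most of the change in the
first quarter hour and 99.3% of it inside the 30-minute session, so the
end-of-session state is essentially the steady state. During Deadaptation
the factor relaxes back toward 1 with the same time constant. Only
end-of-practice changes are reported by the underlying human study; the
exponential dynamic and its time constant are the package's model.

The exoskeleton-reported ankle angle is an affine compression of the
biological angle (`exo = 0.44 * bio + 4.8°`), chosen so a 25° biological
range of motion is reported as 11° — the unpowered-condition encoder
discrepancy. The generator applies one fixed affine map across conditions.

During the Powered condition the generator *runs the package's own
controller*: it calibrates on the subject's Unpowered soleus EMG, commands
torque from the Powered soleus EMG, and adds that torque (per body mass)
to the biological ankle moment template to form the measured total ankle
moment. The analysis side later recomputes exactly the same calibration
and torque from the recorded channels, so the decomposition identity
`total = biological + exoskeleton` holds to machine precision — a tested
invariant, not an approximation.

### Calibration of the defaults

The generator's mechanical templates and soleus burst shape were
calibrated once, at design time, so that the *measured* pipeline outputs
at the default 12-subject study land in the regime the field reports for
this device class: exoskeleton share ≈ 0.18 of peak total ankle moment,
≈ 0.29–0.31 of peak total ankle power, ≈ 0.29 of positive ankle work, and
an exoskeleton peak power of ≈ 0.57 W/kg; commanded torque onset ≈ 16% of
the cycle with a 55–60% on-duration. These targets are recorded in
`gen_config()$target_shares` as the simulation ground truth, and the
acceptance suite checks that the pipeline recovers them from raw signals.

### What the generator deliberately does not emulate

* **Between-subject variability is small.** The human study's defining
  feature was enormous inter-individual spread (soleus changes from −37%
  to +35%), which made its group effects non-significant. The generator
  defaults use a 2-point SD on the steady-state change so that parameter
  recovery is testable to ±3 points with 12 subjects; consequently the
  pipeline's ANOVAs come out strongly significant and standardized mean
  differences large, *unlike* the human data. Passing recovery tests shows
  the pipeline measures what the generator put in — not that real effects
  of this size would be detectable in humans.
* The biological moment template does not shrink as EMG adapts; the
  measured total moment therefore rises by the exoskeleton contribution
  rather than staying constant.
* No musculoskeletal dynamics, no frontal/transverse kinematics, no
  multi-day training sessions (the timeline is a configuration hook), and
  the affine encoder map cannot reproduce the observation that encoder
  *velocities* at push-off were only mildly compressed relative to the
  range-of-motion compression (see below).

## Analysis choices

**Events and cycles.** Heel strikes / toe-offs are threshold crossings
(20 N) of the vertical GRF, debounced by a minimum-interval rule. Each
stride is linearly resampled onto 101 points (0–100%, heel contact at 0);
per-stride stance end is taken from the detected toe-off.

**Joint power.** Angular velocity is obtained by centered finite
differences on the 101-point grid using each stride's duration (one-sided
at the ends). At the default cadence the grid step (≈ 11 ms) matches the
mechanics sampling resolution, and the sinusoid closed-form tests bound the
discretization error below 0.5%; work is trapezoidal integration of the
positive and negative parts of power over stride time.

**Decomposition shares.** Component curves are ensemble means; shares are
`peak(exo)/peak(total)` for moment and power and the positive-work ratio,
matching the "peak of the mean curve" convention used for such figures.
The exoskeleton power uses angular velocity from the *biological* angle by
default (`velocity_source = "exo"` switches to the encoder angle). Under
the affine encoder map, encoder velocities are scaled by 0.44, which would
make the published share regime (power share 0.29 alongside moment share
0.18) internally impossible; the empirical observation that powers
computed from encoder angles were only ~15% lower also implies real
encoder velocity at push-off is nearly biological. Velocity from the
biological angle is therefore the defensible default in this model.

**EMG metrics.** Envelopes are normalized per subject and muscle to the
maximum of the BootsOnly *mean* curve (robust to single-sample spikes);
RMS is taken over stance (plantar flexors) or swing (tibialis anterior),
per stride and then averaged (`pooled = TRUE` pools samples instead).
Percent change is `100 * (b - a) / a`; the standardized mean difference is
`|mean_a - mean_b| / ((sd_a + sd_b)/2)`, flagged "small" below 0.3.

**Scalar statistics.** The six-window comparison uses a repeated-measures
one-way ANOVA by default (subjects cross conditions), with the classical
one-way model as a comparison mode; Tukey HSD post-hocs attach only when
the omnibus test is significant at 0.05. Both are driven by `stats::aov` /
`TukeyHSD` and verified against hand-computed sums of squares in the
tests.

**Curve-level statistics.** One-dimensional statistical parametric mapping
is implemented by max-statistic permutation rather than random-field
theory: condition labels of subject-mean curves are permuted, the null
distribution of the curve-wide maximum F sets the critical threshold, and
suprathreshold clusters get cluster-mass permutation p-values. Permutation
inference is assumption-light and exactly testable: the family-wise error
over 500 null simulations is asserted to sit at 0.05 ± 0.02. P-values use
the `(b + 1)/(n_perm + 1)` convention, so the smallest attainable p is
`1/(n_perm + 1)` and the test is exact at level α under exchangeability.

**Power analysis.** `paired_t_sample_size()` scans n for the smallest
exact noncentral-t power reaching the target. At d = 0.5, α = 0.05,
two-tailed, 80% power it returns 34. At d = 0.97 one-tailed it returns 9:
the power at n = 8 is 0.794, a hair under the target, which is why
software reporting fractional n (8.1) rounds to 8 for this textbook case.

## Numerical and reproducibility details

* Same configuration (including seed) ⇒ byte-identical datasets and
  reports; all randomness flows from explicit seeds, and internal seeding
  restores the caller's RNG state.
* Filtering is restricted to a 5-s padded segment around each analysis
  window; the pad exceeds the filters' settling times by orders of
  magnitude, so segment results are numerically identical to
  full-recording results inside the window (and the analysis runs ~10×
  faster).
* Trial CSVs serialize doubles with 17 significant digits, so a
  write/read round trip is exact; units and rates travel in a JSON
  sidecar.
* Degenerate inputs fail loudly: all-zero calibration envelopes, empty
  phase windows, zero reference maxima, non-monotone time stamps, < n
  available strides (the error names the shortfall), negative transmission
  ratios, and aliasing sampling rates are all errors, not warnings.

### Problem sizes used by the test and acceptance suites

The default study (12 subjects × 50 minutes, EMG at 1000 Hz) is what the
acceptance suite runs — about a minute of compute. Unit tests use a
shrunken timeline (1/1/2/1 minutes, two subjects) that preserves every
structural property (> 30 strides per condition, calibration window
length, all six analysis windows); the SPM calibration uses 500 null
simulations of 3 × 8 curves with 199 permutations each. These sizes are
the package's own choices balancing statistical resolution against a
test suite that runs in a couple of minutes.

## Known limitations

* The generator's realism is "shape-level": templates are smooth splines
  with additive/multiplicative noise, not biomechanically simulated gait.
* Encoder discrepancy is affine; soft-tissue dynamics that make the
  encoder lag direction-dependently are not modelled.
* The repeated-measures ANOVA assumes sphericity (no correction is
  applied), matching common practice for six-condition gait tables.
* SPM inference permutes across subjects' condition labels freely; a
  within-subject restricted permutation scheme would be tighter for
  strongly subject-structured data.
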