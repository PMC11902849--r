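---
title: "Motion segment size from a single wrist-worn IMU"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion segment size from a single wrist-worn IMU}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
```

```{r setup}
library(wristmss)
```

## 1. Why segment sizes

After a stroke, reaching movements of the paretic arm are not only
smaller and slower but *fragmented*: instead of one smooth sweep, the
limb advances in a sequence of short sub-movements separated by
direction reversals. A statistic that is sensitive to both the scale and
the fragmentation of movement is the **motion segment size**. Take any
scalar kinematic signal sampled at times $t = 1, 2, \dots$ — here a
Euler angle of the wrist or one acceleration axis — and cut it at every
direction reversal, i.e. wherever the first difference changes sign. A
*motion segment* is one maximal monotone run, and its size is

$$\mathrm{MSS} = \sum_{t \in \text{run}} |x_t - x_{t-1}|,$$

the total variation of the signal over the run. Two properties make this
decomposition well behaved and are enforced by tests:

* **Conservation.** Adjacent segments share their boundary extremum, so
  the first differences partition exactly and the segment sizes sum to
  the total variation of the whole signal, $\sum_t |x_t - x_{t-1}|$.
* **Refinement invariance.** Inserting extra samples inside a monotone
  run (e.g. by upsampling) changes no segment size, because total
  variation of a monotone stretch depends only on its endpoints.

The **average MSS** of a recording is the mean size of segments that
exceed a noise threshold — 10° for the angular signals, 0.05 m/s² for
acceleration, following the clinical protocol this package reproduces.
The thresholds reject sensor-noise wiggles that would otherwise flood
the average with near-zero segments. Filtering is *strict* (`size >
threshold`), and when no segment qualifies the average is `NA`: an
absence of measurable movement is not the same as zero movement, and
conflating them would bias correlations. A useful calibration case: a
sampled sinusoid of amplitude $A > $ threshold$/2$ decomposes into
peak-to-trough segments of size $2A$, so its average MSS is $2A$ up to
one sample step of the peak slew rate.

```{r sine}
t <- seq(0, 8, by = 1 / 25)
seg <- segment_signal(30 * cos(pi * t))
average_mss(seg$size, threshold = 10)
```

A `plateau` policy decides what happens when the derivative is exactly
zero for a while: `"extend"` (default) treats a flat stretch as part of
the ongoing run, `"break"` ends the run at the plateau. Real IMU streams
almost never contain exact plateaus, but resampled or quantised signals
can, and both policies conserve total variation.

## 2. From gyroscope rates to Euler angles

The smartwatch gives body-frame angular velocity
$\boldsymbol\omega$ (deg/s) and specific force (m/s²) at a nominal
25 Hz. Orientation is reconstructed by strapdown integration:

1. **Calibration.** The first second of each recording (the protocol's
   button-press pause, forearm pronated on the desk) is averaged to give
   the gyro bias and the gravity reference; the calibration pose defines
   the zero of all three angles. The window is half-open
   $[t_0, t_0 + 1\,\mathrm{s})$. Guards flag motion inside the window
   (gyro SD above 3 deg/s) and an implausible gravity magnitude
   (outside 8.0–11.6 m/s²).
2. **Integration.** With uniform sampling at step $\Delta t$, each
   bias-corrected rate sample is applied over the following step via the
   rotation-matrix exponential (Rodrigues' formula) of
   $[\boldsymbol\omega_k]_\times \Delta t$:
   $R_{k+1} = R_k \exp([\boldsymbol\omega_k]_\times \Delta t)$.
   This first-order hold is exact for constant single-axis rotation and
   second-order accurate for smooth multi-axis motion; tests compare it
   against an independent quaternion integrator running at a 100× finer
   step. Non-uniform recordings must be passed through
   `resample_uniform()` first — the integrator refuses them rather than
   silently assuming a step size.
3. **Angles.** Intrinsic z-y-x (yaw–pitch–roll) Euler angles are
   extracted, unwrapped to be continuous across ±180°, and flagged near
   the gimbal singularity (|pitch| > 85°), where roll carries its
   previous value. In the intended wrist geometry pitch stays far from
   ±90°.

Roll, pitch, and yaw are then proxies for forearm
pronation/supination, elbow flexion/extension, and shoulder rotation.
This is a deliberate single-sensor simplification: absolute anatomical
joint angles are not identifiable from one wrist IMU, but the
*statistic* of the angle streams does not require them to be.

Acceleration enters the segment analysis either raw or with the static
calibration component removed (`"static_removed"`, the default): the
constant calibration-frame gravity vector is subtracted in sensor
coordinates. During rotation this leaves a gravity-projection residual —
accepted by the protocol, since MSS of acceleration responds to
movement vigour rather than to an exact linear-acceleration estimate.

## 3. Statistics

Average MSS per subject, domain, and signal is correlated with the
clinical score by **Spearman's rank correlation**: midranks for ties,
$r_s$ as the Pearson correlation of rank vectors, and a two-sided
p-value from the $t$ approximation with $n - 2$ degrees of freedom, the
convention of mainstream clinical statistics software. For very small
samples ($n \le 8$) an exact permutation p-value over all $n!$ rank
permutations is available (`p_method = "exact"`); beyond that the full
enumeration is intractable in pure R and the request is refused rather
than silently approximated. The hand-rolled implementation is
cross-checked in the tests against `stats::cor.test`.

Pre/post change summaries pair each subject's baseline and follow-up
values, exclude (with a warning) subjects missing a session, and report
mean ± SD (the $n-1$ denominator) of the per-subject deltas.

Correlation grids are computed with pairwise deletion per cell; cells
with fewer than three complete pairs remain in the grid as undefined
(`--`) so the 5 × 7 report shape is stable. The bundled score fixtures
(13 records: 9 baseline, 4 follow-up) reproduce the published values
exactly — Spearman ARAT–FMUE 0.938 and ARAT–MBI 0.812, mean age 61.3 ±
14.5, median onset 28 days — which `verify_fixtures()` recomputes on
demand. Published one-decimal figures are compared at half an ulp of
that precision (±0.05), since the source tables round half-up while R
rounds half-to-even.

## 4. The synthetic cohort generator

The clinical recordings behind the protocol are not public, so the
generator is a first-class component, not a test shim. Each subject
carries an impairment severity $s \in [0, 1]$ that drives every
degradation channel at once:

* **Amplitude attenuation.** Nominal per-domain angular excursions
  (e.g. 45° roll, 40° pitch, 60° yaw in the gross-movement domain 4)
  shrink by the factor $1 - 0.6 s$.
* **Slowing.** Stroke duration grows by $1 + s$, so performance time
  increases with severity.
* **Fragmentation.** A two-tone oscillation centred on 4 Hz with a one
  second onset ramp rides on the movement; its amplitude grows linearly
  with $s$ (0.5° at $s = 1$).
* **Scores.** ARAT, FMUE, and MBI are monotone decreasing maps of $s$
  with integer noise, clipped to their scale ranges (0–57, 0–66,
  0–100).

Movements are minimum-jerk strokes ($10\tau^3 - 15\tau^4 + 6\tau^5$ and
its derivatives), alternating outward and return. Body-frame angular
rates are derived from the Euler-angle trajectories through the exact
Euler-rate-to-body-rate kinematics, so integrating the generated
gyroscope stream recovers the constructed angles — a closed-loop
construction oracle used throughout the tests. Acceleration is the
second time-derivative of a displacement profile plus a constant
gravity vector and white noise; gravity is deliberately *not* rotated
with the wrist, which keeps the `"static_removed"` mode an exact
construction oracle at the cost of some realism. Each recording starts
with a one second static window so the standard calibration step
applies unchanged. One cohort seed fans out into independent
per-recording substreams, so any single recording is reproducible
without generating the rest.

The tremor amplitude deserves a note, because it is the generator's most
delicate constant. A direction reversal occurs wherever total angular
rate crosses zero, so tremor fragments the signal only where its peak
rate $2\pi f a$ exceeds the sweep rate. At the default 0.5° (severity 1)
the tremor's peak rate (~12.6 deg/s) sits at the level of the *slowest*
gross sweep (~11 deg/s at $s = 1$), so fragmentation erodes sweep
endpoints progressively with severity. Much larger amplitudes put the
whole recording in the tremor-dominated regime: every segment becomes a
tremor swing whose size *grows* with severity, and the
threshold-filtered average loses its monotone relation to impairment.
At the chosen default, the severity–MSS relation is monotone and the
domain-4 roll average MSS correlates positively with the generated ARAT
in 100 of 100 seeded 20-subject replicates.

What the generator does *not* emulate: rotated gravity and centripetal
accelerations, sensor-axis misalignment, magnetometer effects, task-
specific grasp kinematics, compensatory trunk motion, and the floor/
ceiling idiosyncrasies of real ARAT item scoring. Severely impaired
synthetic subjects ($s \gtrsim 0.85$) produce no above-threshold angular
segment in any domain and yield `NA` averages — a deliberate portrayal
of the statistic's real failure mode at the bottom of the scale.

## 5. A full run

```{r pipeline}
cfg <- pipeline_config(synthetic = synthetic_config(n_subjects = 8, seed = 42))
report <- run_pipeline(cfg)
report
```

```{r tidy}
glance(report)
dplyr::filter(tidy(report$correlations), domain == "4")
```

The per-domain recordings are also pooled per subject into `"whole"`
rows — segment lists concatenated, performance times summed — before
the grid is computed, mirroring the whole-test analysis of the
protocol. With follow-up sessions enabled
(`synthetic_config(followup = TRUE)`), the report adds domain-4 angular
change summaries over completers.

```{r plot}
autoplot(report$correlations)
```

## 6. Numerical choices, collected

* Segment boundaries share the extremum sample; sizes partition total
  variation exactly (tested property, not an approximation).
* Strict `>` threshold filtering; empty filter result is `NA`.
* Rotation-matrix exponential per step; no small-angle approximation.
* Half-open windows everywhere (calibration window, domain splits).
* Spearman p-values: $t$ approximation by default; exact enumeration
  only for $n \le 8$.
* Angle unwrapping by multiples of 360°, carrying continuity across the
  recording.
* Resampling is linear interpolation onto a uniform grid anchored at
  the first timestamp; MSS is refinement-invariant, so modest
  upsampling does not distort segment sizes.

Problem sizes throughout are small: recordings of $10^2$–$10^4$
samples, cohorts of tens of subjects; every operation is vectorised or
$O(n)$ per recording, and a 20-subject, 80-recording pipeline runs in
well under a minute on one CPU.
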