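---
title: "Measuring head stabilization from dual body-worn IMUs: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring head stabilization from dual body-worn IMUs: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the science and the engineering decisions behind
`headstab`: the signal model, each estimator with its assumptions and
defaults, what the synthetic-data generator does and does not emulate, and
the numerical corner cases. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The measurement problem

Two inertial measurement units (head and trunk) record specific force (g)
and angular velocity (rad/s) at a nominal 100 Hz on independent clocks. The
quantities of interest — attenuation coefficients, harmonic ratios,
coherences, phase differences — are defined per detected step, in a
gravity-aligned frame, over whatever walking the subject happened to do. The
chain from raw files to measures is: synchronize, calibrate, estimate
gravity/orientation, align, detect steps, exclude cycling, group bouts,
compute spectra and measures, summarize by predominant frequency.

## Conventions

Quaternions are scalar-first Hamilton quaternions encoding active rotations:
`quat_rotate(q, v)` rotates `v` about the axis of `q` by its angle,
right-handed. Gyroscopes measure the right-handed body rate, under which a
world-fixed vector `g` observed in the body frame evolves as
`dg/dt = -omega x g`. The body/aligned frame is right-handed with x anterior,
y medial/lateral pointing left, z vertical up; a static, calibrated sensor
measures +1 g along +z. The orientation output `q(t)` is the minimal
rotation taking the world vertical onto the sensor-frame gravity estimate;
rotating by `q(t)^-1` maps sensor vectors into the aligned frame, which is
world-fixed in roll and pitch but stays body-fixed in yaw (the rotation axis
is horizontal by construction, so the transform carries no yaw — asserted to
1e-9 in the tests).

## Clock synchronization

The two devices are knocked together at the start and end of a session.
Knocks are found as acceleration-magnitude excursions above 2.5 g with a 1 s
refractory period; the event time is refined by three-point parabolic
interpolation of the magnitude peak. Sub-sample timing matters: a linear
drift fit across a pair of events several minutes apart needs timing noise
well below one 10 ms sample to resolve drifts near 1e-5 s/s. The map is
`head_time = offset + (1 + drift) * trunk_time`, solved exactly through the
two event pairs; modeling drift as linear between exactly two knocks is the
only identifiable choice. Head channels are brought onto the trunk clock by
cubic-spline resampling — linear interpolation would shave several percent
off harmonics near 20 Hz and bias the attenuation coefficients.

## Calibration

The static posture pins the body vertical: the rotation must take the mean
measured gravity direction to +z. The five pitch nods pin the
medial/lateral axis: the nod rotation axis is estimated as the first
principal axis of the nod-segment angular-velocity samples (the constraint
is stated by the protocol, the estimator is ours), with its sign chosen so
that the first strong nod sample is a forward pitch. The body frame is
completed by Gram–Schmidt. The trunk device has no nod routine; its
calibration is the minimal tilt aligning gravity, which leaves yaw
unconstrained — acceptable because the trunk mounting (a belt) fixes yaw
mechanically, and is why the generator's default trunk mounting error is a
pure tilt. Degenerate inputs are rejected: non-static static segments
(|mean a| off 1 g by more than 5%) and nod axes within about 25 degrees of
gravity.

## Gravity filter

Per sample: (1) rotate the previous gravity estimate by the inverse of the
gyroscope increment (exact axis-angle rotation, not its first-order cross
product, so pure-gyro integration is exact up to the piecewise-constant-rate
assumption); (2) blend with the low-passed accelerometer,
`g <- alpha * g + (1 - alpha) * a`; (3) normalize. The blend is written as a
convex combination: with `|g| = 1` it is equivalent to the additive update up
to a reparameterization of `alpha`, and it makes the limiting cases exact
(`alpha = 1` pure gyro, `alpha = 0` pure accelerometer — both asserted in
tests). Inputs are prefiltered with 5th-order zero-phase Butterworth filters
(gyro high-passed at 0.1 Hz against bias drift, accel low-passed at `f_lp`
against transients), using odd-reflection end padding because a 0.1 Hz
high-pass otherwise rings over tens of seconds at the recording edges.
Zero-phase filtering is a deliberate offline choice; a causal filter would
add a frequency-dependent lag to the gravity estimate.

Defaults `alpha = 0.998` and `f_lp = 1` Hz were chosen by a grid search over
`alpha` in 0.9–0.999 and `f_lp` in 0.5–2 Hz on synthetic tilt trajectories
with gait-band dynamics and default sensor noise, minimizing the median
geodesic orientation error. The result is insensitive to `f_lp`; accuracy
improves monotonically toward `alpha = 0.999` on these trajectories, and we
back off slightly to keep a larger accelerometer correction margin for real
devices whose gyro scale and bias behave worse than the simulation. The
complementary-filter time constant `dt * alpha / (1 - alpha)` is then about
5 s: long enough that the filter tracks 2 Hz tilt oscillations through the
gyro (first-order tracking error `1/(omega * tau)`, under 2% at 1.86 Hz)
rather than fighting them with the lagging accelerometer direction. Error is
measured as the geodesic distance `acos(2 <q1, q2>^2 - 1)`, the angle of the
shortest arc between orientations, cross-checked in the tests against a
brute-force relative-rotation oracle.

Degenerate cases: a vanishing blended estimate keeps the previous direction;
a gravity estimate antiparallel to the world vertical has no defined minimal
rotation, so the previous quaternion is held. Both are counted and reported.

## Step detection and exclusions

Steps are peaks of aligned vertical trunk acceleration with height ≥ 0.2 g,
prominence ≥ 0.4 g and separation ≥ 0.2 s. The 0.2 s separation encodes the
5 Hz maximum detectable step frequency. Filters apply in the order height,
distance, prominence (a taller neighbor suppresses peaks within 0.2 s even
if it is itself later dropped for prominence); among equal heights the
earlier sample wins. The implementation was validated against a frozen
reference case from an independent peak-detection implementation.

Cycling produces step-like vertical spikes; it is excluded per step when the
vertical RMS falls below 0.1 g OR the vertical and medial/lateral
predominant frequencies (from 1024-sample classification spectra) differ by
more than 0.5 Hz. These two thresholds are package defaults fitted once
against the synthetic cycling generator, and both are exposed in the
configuration. Surviving steps are grouped into bouts wherever consecutive
peaks are less than 1 s apart (peak-to-peak, an assumption the protocol does
not state); single-step bouts are discarded. Analysis is finally gated to
steps whose head vertical predominant frequency lies in [1, 2.6] Hz, the
band in which predominant frequency is an established proxy for walking
speed.

A practical caveat the tests encode explicitly: for bouts of only two or
three steps, the 5–10 s classification windows are mostly non-gait, and such
steps are occasionally misclassified as cycling. Bout-boundary recovery is
therefore exact for bouts of at least four steps, while the shortest bouts
can be lost to the per-step exclusions (never split or merged across rest
gaps, which all exceed 1.5 s in the generator).

## Spectra, frequencies, RMS

Short-time spectra are Blackman-windowed periodograms of step-centered
segments — 1024 samples for cycling classification, 512 for all analysis
quantities (a temporal-resolution compromise for short bouts). One-sided
power is normalized so its sum equals the mean square of the windowed
segment (Parseval, asserted to 1e-9); only ratios and argmaxes are consumed
downstream, so the convention is immaterial there. Edge segments are
zero-padded symmetrically. The predominant frequency is the power argmax
excluding the DC bin (gravity residuals would otherwise win), ties toward
the lower frequency. RMS uses unwindowed samples, except inside the
attenuation coefficient where both head and trunk segments are
Blackman-weighted to de-emphasize non-locomotor content at segment edges —
any common window cancels in the RMS ratio to first order.

## The four stability measures

**Attenuation coefficient.** `AC = 1 - A_H / A_T` per axis; positive values
mean head accelerations are attenuated relative to the trunk. Zero trunk RMS
yields a missing value and the step is excluded from AC summaries.

**Harmonic ratio.** The stride (two steps) is the fundamental gait period,
so with per-axis predominant frequency `f_dom` the biphasic (AP, V) axes
concentrate power at the even stride harmonics `k * f_dom` and the ratio is
even over odd, `sum_{k=1..10} S(k f_dom) / sum_{k=1..10} S((2k-1) f_dom/2)`;
the monophasic ML axis is scored with the inverted ratio. Each harmonic is
read from the single nearest grid bin; harmonics at or above Nyquist are
truncated; a zero denominator returns a configurable cap (default 100)
rather than infinity. Note the harmonic ladder is defined on the stride base
`f_dom / 2`: an even/odd split defined on multiples of `f_dom` alone cannot
produce the odd ("out-of-phase") harmonics the measure is meant to capture —
this indexing is the one consistent with the biphasic/monophasic rationale,
and it is the main place where a reader comparing formula transcriptions
should pay attention.

**Coherence.** A single 512-sample segment has ill-defined coherence, so a
1024-sample window centered on the step is split into exactly five
Blackman-windowed 512-sample sub-segments advanced by 128 samples, and
`K^2 = |S_xy|^2 / (S_xx S_yy)` is evaluated at the grid bin nearest `f_dom`
(no interpolation). Values are clamped into [0, 1] against floating-point
overshoot. With this much overlap the estimator has a large positive bias
under independence — the test suite measures it by Monte Carlo against a
naive re-implementation — which is acceptable here because the measure is
used comparatively across frequency bins, not as an absolute significance
test.

**Phase difference.** The lag of the cross-correlation maximum between
512-sample mean-removed, Blackman-weighted segments, searched within one
period of the reference signal, divided by that period (from the first
non-zero-lag autocorrelation peak exceeding a quarter of the zero-lag value,
a guard against noise ripples) and multiplied by 2 pi. Both the
cross-correlation peak and the period are refined by three-point parabolic
interpolation: the raw 10 ms lag grid quantizes phase to about 6.7 degrees
at 1.86 Hz, coarser than the 3-degree recovery the validation demands.
Because acceleration is compared against angular velocity while the
literature compares displacement against angle, a correction of
`2(-pi/2) - (-pi/2) = -pi/2` is added (each sinusoidal integration shifts
phase by -pi/2 — re-derived numerically in the acceptance suite); results
are wrapped to (-pi, pi]. Aperiodic reference segments yield a missing
value. Rotational signals stay in the body frame (pitch velocity is the
calibrated ML gyro component); they are deliberately not rotated into the
aligned frame.

## Summaries and effect size

Boxplot statistics (type-7 interpolated quartiles, whiskers to the most
extreme samples within 1.5 IQR, outliers counted but not listed) are
computed per spectral-grid frequency bin (spacing 100/512 Hz) across
[1, 2.6] Hz. The effect of predominant frequency on each measure is
summarized by the Kruskal–Wallis-based effect size
`eta^2 = (H - k + 1)/(n - k)` with the grid bins as groups (the natural
discrete grouping; the original analysis does not state a coarser binning),
labeled small (< 0.04), intermediate, or large (> 0.11). `H` is tie-corrected
(`stats::kruskal.test`), cross-checked in the tests against an exhaustive
rank oracle on tie-free samples; near-identical groups can produce slightly
negative `eta^2`, which is reported as computed and labeled small.

## The synthetic session generator

`generate_session()` builds a miniature recording day on a common master
clock: a knock (3 g, 50 ms half-sine, synchronized across devices) near each
end, a 4 s static posture and five 1 Hz pitch nods for calibration, then
alternating rest gaps (2.5 s minimum plus an exponential tail) and walking
bouts, with one optional cycling segment. Its default parameters are the
study conditions the analysis targets:

* per-bout step frequency drawn from N(1.86, 0.23) Hz, with small
  autoregressive within-bout jitter (SD 0.03 Hz, 0.5 s correlation time —
  the within-bout variability model is a free choice, reported variances
  only constrain its scale);
* bout lengths from a discrete power law with exponent 1.5 truncated to
  [2, 2000] steps (log-log-linear decay; the exponent is configurable
  because no fitted value is published);
* vertical RMS per bout lognormal with mode 0.3 g, truncated to
  [0.9, 4/3] of the mode;
* trunk gait acceleration as a harmonic series on the step phase: even
  stride harmonics with geometric decay 0.4 per harmonic, odd stride
  harmonics scaled to hit per-axis harmonic-ratio targets (defaults 4, 2.5,
  6 for AP/ML/V), all-cosine phases so each step produces one sharp peak;
* head channels equal to the trunk channels attenuated per axis by the
  configured attenuation coefficients (defaults 0.3, 0.2, 0.05 for AP/ML/V)
  plus independent sensor noise;
* head and trunk pitch velocity as sinusoids at the step frequency
  phase-locked so the corrected displacement-vs-angle phase equals the
  configured target (default -50 degrees);
* device orientation equal to the integral of the pitch velocity (bounded
  analytic pitch angle), so gyroscope, gravity and orientation truth are
  mutually consistent;
* white accelerometer/gyroscope noise (0.02 g, 0.01 rad/s), constant-rate
  gyro bias drift (0.05 rad/s per hour), mounting rotations to be undone by
  calibration, and a head clock offset of 0.3 s with 1e-5 drift;
* a cycling segment of narrow 0.55 g vertical pulses at 1.6 Hz cadence with
  low vertical RMS (under 0.1 g) and a 0.8 Hz medial/lateral sway — passing
  the peak detector while failing both gait criteria.

Head signals are evaluated analytically at the master times corresponding to
the head device's clock ticks (the step *phase*, envelopes and angles are
interpolated, never the signals), so the emitted recordings carry the clock
model without any interpolation loss.

Two amplitude clamps are design constraints rather than physiology: the
per-bout RMS truncation keeps every weak (odd) step peak above the
detector's 0.2 g/0.4 g floor with a comfortable noise margin at the bottom,
and keeps gait acceleration magnitude below the 2.5 g knock threshold at the
top, so knock detection, step recovery and bout boundaries are exactly
testable. Real free-living data violate both bounds; passing these tests
therefore demonstrates correctness of the machinery, not robustness to
vigorous running or feeble shuffling. Other simplifications: sensor tilt is
pitch-only (no roll wobble), there is no soft-tissue artifact, no
stair-walking class, no wear-time gaps, no biomechanical forward simulation
of the head-trunk chain, and the harmonic phases are all-cosine (real gait
spreads them). The emitted pitch rate omits the envelope-derivative term of
the analytic pitch angle, a discrepancy confined to the half-period bout
on/off ramps.

One statistical consequence of the heavy-tailed bout-length law is worth
knowing: in a single two-hour session most steps belong to a handful of long
bouts, so the *step-weighted* mean predominant frequency has an effective
sample size of only tens of draws and varies noticeably between sessions,
even though the per-step marginal distribution is exactly N(1.86, 0.23).
Distribution-level validation therefore uses a fixed two-hour session in the
test suite, and multi-session pooling is the route to tighter estimates on
real data.

## Problem sizes used in validation

The test suite validates on 600 s sessions (about 700–900 steps) for the
measure-recovery checks and one 7200 s session (about 11,000 steps, the
scale of Fig-style distribution summaries) for the frequency-distribution
and bookkeeping checks; orientation accuracy uses five 60 s trajectories.
These sizes were chosen so the whole suite exercises every stage at
statistically meaningful step counts while remaining comfortable to run
interactively.

## Known limitations

* The gravity filter estimates tilt only; yaw/heading is unobservable
  without a magnetometer and is deliberately left body-fixed.
* The attenuation coefficient inherits a small negative bias on the AP axis
  from residual gravity leakage at the gait frequency (the head pitches more
  than the trunk); with the default `alpha` this stays within the validated
  0.02 tolerance on noiseless sessions.
* Predominant frequencies are quantized to the 512-sample grid
  (about 0.195 Hz), which slightly inflates the apparent frequency SD and
  bounds the resolution of the frequency-binned summaries.
* Cycling exclusion is threshold-based on two features; a classifier trained
  on labeled data would generalize better to activities the generator does
  not emulate.
* Very short bouts (2–3 steps) sit mostly outside their own analysis
  windows; their spectra, and hence their gating and classification, are
  intrinsically unreliable. This is a property of fixed-length short-time
  analysis, not of the implementation.
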