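# headstab

Head stabilization during walking — the reflexive damping of trunk
accelerations along the kinematic chain to the head, and the pitching of the
head that compensates vertical translation — is a candidate digital biomarker
for balance and gait disorders. Laboratory protocols measure it under
supervision; ecological momentary assessment instead records subjects over a
whole day with two small inertial measurement units (IMUs), one in a cap on
the head and one on a belt at the trunk, and extracts the stabilization
measures from whatever walking actually occurred.

`headstab` implements that full analysis for dual 100 Hz
accelerometer + gyroscope recordings:

* **Synchronization** of the two free-running device clocks from the knock
  events at the start and end of a session (linear offset + drift model).
* **Calibration** of each sensor to a body-fixed frame from a static posture
  and five pitch nods (gravity to vertical, nod axis to medial/lateral).
* **Gravity and orientation estimation** with a lightweight complementary
  filter: the gravity estimate `g(t)` is propagated by the gyroscope
  increment, blended with the low-passed accelerometer with weight
  `1 - alpha`, and normalized; the orientation `q(t)` is the minimal (yaw-free)
  rotation aligning `g(t)` with the world vertical. Net inertial acceleration
  in aligned coordinates is `i_A = rot(q^-1, a - g)`.
* **Step detection** on aligned vertical trunk acceleration (peaks with
  height ≥ 0.2 g, prominence ≥ 0.4 g, separation ≥ 0.2 s), exclusion of
  cycling-like periods (low vertical RMS or mismatched vertical vs.
  medial/lateral predominant frequencies), and grouping into walking bouts
  (inter-step gaps < 1 s, single-step bouts discarded).
* **Short-time spectra** (Blackman-windowed periodograms, 1024 samples for
  classification, 512 for analysis), predominant frequencies and per-segment
  RMS.
* **Head-stability measures** per step, as functions of predominant
  frequency `f_dom`:
  - attenuation coefficient `AC = 1 - A_H / A_T` (head vs. trunk RMS),
  - harmonic ratio `HR = sum_k S(k f_dom) / sum_k S((2k-1) f_dom / 2)`
    (even/odd stride harmonics, N = 10; inverted for the medial/lateral
    axis),
  - Welch magnitude-squared coherence
    `K^2 = |S_xy|^2 / (S_xx S_yy)` at `f_dom` between head pitch velocity and
    vertical head acceleration, and between head and trunk pitch velocity
    (five 512-sample sub-segments of a 1024-sample window),
  - cross-correlation phase difference between vertical head acceleration
    and pitch velocity with the analytic `-pi/2` correction that makes it
    comparable to displacement-vs-angle phase.
* **Summaries**: frequency-binned boxplot statistics on the 512-sample
  spectral grid over 1–2.6 Hz, and the Kruskal–Wallis effect size
  `eta^2 = (H - k + 1) / (n - k)` (small < 0.04, intermediate < 0.11,
  large > 0.11).

Because no public dual-IMU recordings of this kind exist, the package ships a
**synthetic session generator** (`generate_session()`) with complete ground
truth — step times, bout boundaries, per-sample orientation and gravity,
segment labels, clock model, mounting rotations — that reproduces the
statistical structure the analysis assumes (harmonic gait spectra around a
1.86 ± 0.23 Hz step frequency, skewed vertical RMS near 0.3 g, heavy-tailed
bout lengths, phase-locked head pitching, cycling confounders, sensor noise
and clock drift). Every stage is validated against that ground truth.

## Worked example

```r
library(headstab)

params <- gait_params(seed = 42)              # study-like default conditions
ses <- generate_session(params, 600)          # 10-minute session + truth
run <- run_pipeline(pipeline_config(), head = ses$head, trunk = ses$trunk)
run
#> <headstab_run> 811 steps detected | 50 cycling | 0 singleton | 0 out of gate | 761 retained (100.0% of bout steps)
run$sync
#> <sync_model> offset=0.3003 s  drift=9.25e-06 s/s

ret <- subset(run$steps, flags == "retained")
round(c(ac_AP = median(ret$ac_AP), ac_ML = median(ret$ac_ML),
        ac_V = median(ret$ac_V)), 3)
#> ac_AP ac_ML  ac_V
#> 0.285 0.197 0.050
round(median(ret$phase_hv_hp, na.rm = TRUE) * 180 / pi, 1)
#> [1] -50.1
```

The ten-minute recording contained 811 step-like peaks; 50 came from the
embedded cycling segment and were excluded, and every retained step fell in
the 1–2.6 Hz analysis band. The recovered clock offset (0.3003 s) matches the
generator's 0.3 s, the attenuation coefficients match the generator targets
(0.3, 0.2, 0.05 for AP/ML/V: the head moves almost as much vertically as the
trunk but is strongly stabilized horizontally), and the corrected phase
between vertical head acceleration and head pitch velocity recovers the
configured −50°, the value around which head-pitch compensation of vertical
translation is known to cluster.

Frequency-binned summaries and effect sizes are in `run$summaries` and
`run$effects`:

```r
run$effects[run$effects$measure %in% c("ac_AP", "coh_hp_hv"), 1:3]
#>      measure eta_squared label
#>        ac_AP 0.002920996 small
#>    coh_hp_hv 0.133782476 large
```

A thin command-line interface wraps the same functions:

```sh
Rscript inst/scripts/headstab-cli.R simulate --duration 600 --seed 1 --out session/
Rscript inst/scripts/headstab-cli.R run --head session/head.csv \
    --trunk session/trunk.csv --out session/results/
Rscript inst/scripts/headstab-cli.R summarize --steps session/results/steps.csv \
    --out session/summaries/
```

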