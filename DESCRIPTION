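Package: headstab
Title: Head Stabilization Metrics from Dual Body-Worn Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ecological momentary assessment of head stabilization
    during gait from two synchronized body-worn inertial measurement units
    (head and trunk). Implements device synchronization from knock events,
    sensor-to-body calibration from static and nodding postures, per-sample
    gravity and orientation estimation with a lightweight sensor-fusion
    filter, transformation of accelerations into a gravity-aligned frame,
    peak-based step detection with exclusion of cycling-like motion, grouping
    of steps into walking bouts, short-time spectral analysis (predominant
    frequency, RMS), and four per-step head-stability measures: attenuation
    coefficient, harmonic ratio, magnitude-squared coherence, and corrected
    phase difference. A synthetic dual-IMU gait generator with full ground
    truth supports validation of every stage, and frequency-binned summaries
    with a Kruskal-Wallis eta-squared effect size reproduce study-style
    outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
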