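test_that("generator parameters are validated", {
  expect_error(gait_params(step_freq_mean = -1))
  expect_error(gait_params(ac_targets = c(AP = 1.2, ML = 0.2, V = 0.1)))
  expect_error(gait_params(n_harmonics = 0))
  expect_error(gait_params(accel_noise_sd = -0.1))
  expect_error(generate_session(gait_params(), 30), class = "session_too_short")
})

test_that("identical parameters and seed give bit-identical sessions", {
  a <- generate_session(gait_params(seed = 3), 90)
  b <- generate_session(gait_params(seed = 3), 90)
  expect_identical(a$head$accel, b$head$accel)
  expect_identical(a$trunk$gyro, b$trunk$gyro)
  expect_identical(a$truth$step_times, b$truth$step_times)
  d <- generate_session(gait_params(seed = 4), 90)
  expect_false(identical(a$trunk$accel, d$trunk$accel))
})

test_that("a deterministic-frequency continuous bout yields evenly spaced steps", {
  p <- plain_params(step_freq_mean = 2, step_freq_sd = 0,
                    within_bout_jitter_sd = 0,
                    bout_length_law = list(exponent = 1, min = 100000L,
                                           max = 100000L),
                    seed = 1)
  ses <- generate_session(p, 600)
  expect_equal(length(unique(ses$truth$step_bouts)), 1L)
  gaps <- diff(ses$truth$step_times)
  expect_equal(gaps, rep(0.5, length(gaps)), tolerance = 1e-9)
})

test_that("head gait channels are the trunk channels attenuated per axis", {
  p <- plain_params(ac_targets = c(AP = 0.3, ML = 0.2, V = 0.5),
                    within_bout_jitter_sd = 0, seed = 2)
  ses <- generate_session(p, 300)
  gait <- ses$truth$labels == "gait"
  # with identity mounting and zero pitch the vertical inertial component is
  # accel_z - gravity on both devices
  hv <- ses$head$accel[gait, 3] - 1
  tv <- ses$trunk$accel[gait, 3] - 1
  expect_equal(sqrt(mean(hv^2)) / sqrt(mean(tv^2)), 0.5, tolerance = 1e-6)
  hap <- ses$head$accel[gait, 1]; tap <- ses$trunk$accel[gait, 1]
  expect_equal(sqrt(mean(hap^2)) / sqrt(mean(tap^2)), 0.7, tolerance = 1e-6)
})

test_that("drawn per-bout step frequencies match the configured distribution", {
  # accumulate bouts across seeded sessions until 10,000 steps were drawn
  p <- gait_params(seed = 7)
  draws <- numeric(0)
  steps <- 0L
  k <- 0L
  while (steps < 10000L) {
    k <- k + 1L
    ses <- generate_session(gait_params(seed = 7 + k), 1800)
    draws <- c(draws, ses$truth$bouts$base_freq)
    steps <- steps + length(ses$truth$step_times)
  }
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - p$step_freq_mean), 3 * se)
  expect_lt(abs(sd(draws) - p$step_freq_sd), 0.05)
})

test_that("noiseless step peaks exceed the detector floor and are all found", {
  ses <- generate_session(plain_params(seed = 5), 400)
  v <- ses$trunk$accel[, 3] - 1
  pk <- detect_step_peaks(v, 100)
  # every true step recovered exactly once (the signal is noise-free)
  expect_equal(length(pk), length(ses$truth$step_times))
  expect_lt(max(abs(ses$trunk$t[pk] - ses$truth$step_times)), 0.03)
  expect_true(all(v[pk] > 0.2))
})

test_that("phase and spectral structure are self-consistent", {
  ses <- noiseless_session()
  truth <- ses$truth
  # pick a step well inside a long bout
  long_bout <- truth$bouts$bout[which.max(truth$bouts$n_steps)]
  in_bout <- which(truth$step_bouts == long_bout)
  mid <- in_bout[ceiling(length(in_bout) / 2)]
  ctr <- round(truth$step_times[mid] * 100) + 1L
  # trunk vertical periodogram peaks at the drawn frequency within one bin
  sp <- step_spectrum(ses$trunk$accel[, 3] - mean(ses$trunk$accel[, 3]),
                      ctr, 512L, 100)
  f_bout <- truth$bouts$base_freq[truth$bouts$bout == long_bout]
  expect_lt(abs(predominant_frequency(sp) - f_bout), 100 / 512)
})

test_that("displacement-vs-angle phase locks to the configured target", {
  p <- plain_params(pitch_velocity_amp = c(head = 0.6, trunk = 0.4),
                    within_bout_jitter_sd = 0, seed = 6)
  ses <- generate_session(p, 300)
  truth <- ses$truth
  long_bout <- truth$bouts$bout[which.max(truth$bouts$n_steps)]
  in_bout <- which(truth$step_bouts == long_bout)
  mid <- in_bout[ceiling(length(in_bout) / 2)]
  ctr <- round(truth$step_times[mid] * 100) + 1L
  hv <- ses$head$accel[, 3] - 1         # vertical head acceleration
  hp <- ses$head$gyro[, 2]              # head pitch velocity
  ph <- phase_difference(hv, hp, ctr)
  expect_lt(abs(ph - p$head_pitch_phase) * 180 / pi, 1)
})

test_that("cycling segments trip the detector but fail the gait criteria", {
  cyc <- generate_cycling_segment(60)
  pk <- detect_step_peaks(cyc$accel[, 3], 100)
  n_cycles <- 60 * 1.6
  expect_gte(length(pk), n_cycles - 3)
  # vertical RMS below a same-cadence walking segment
  walk <- generate_session(plain_params(step_freq_mean = 1.6, step_freq_sd = 0,
                                        seed = 8), 120)
  gait <- walk$truth$labels == "gait"
  expect_lt(sqrt(mean(cyc$accel[, 3]^2)),
            sqrt(mean((walk$trunk$accel[gait, 3] - 1)^2)))
  # V and ML predominant frequencies disagree by more than the threshold
  ctr <- 30 * 100
  fv <- predominant_frequency(step_spectrum(cyc$accel[, 3], ctr, 1024L, 100))
  fml <- predominant_frequency(step_spectrum(cyc$accel[, 2], ctr, 1024L, 100))
  expect_gt(abs(fv - fml), 0.5)
})

test_that("session layout has knocks, calibration segments and partitioned labels", {
  ses <- noisy_session()
  segs <- ses$truth$segments
  expect_setequal(unique(c("rest", "gait", "knock", "cycling",
                           "calibration-static", "calibration-nod")),
                  unique(segs$label))
  # segments partition the timeline
  expect_equal(segs$start[-1], segs$end[-nrow(segs)], tolerance = 1e-9)
  expect_equal(segs$start[1], 0)
  expect_equal(segs$end[nrow(segs)], 600, tolerance = 0.02)
  expect_true(all(diff(ses$truth$step_times) > 0))
  # orientation truth is unit-norm
  expect_lt(max(abs(sqrt(rowSums(ses$truth$orientation_head^2)) - 1)), 1e-9)
})

test_that("ground-truth sidecar round-trips segments, steps and parameters", {
  ses <- noisy_session()
  path <- tempfile(fileext = ".csv")
  write_ground_truth(ses$truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$steps$time, ses$truth$step_times)
  expect_equal(back$steps$freq, ses$truth$step_freqs)
  expect_equal(nrow(back$segments), nrow(ses$truth$segments))
  expect_equal(unname(back$params["clock_offset"]), ses$truth$clock_offset)
  expect_equal(unname(back$params["ac_AP"]),
               unname(ses$truth$ac_targets[["AP"]]))
  unlink(path)
})

test_that("orientation trajectories integrate their own gyroscope", {
  # constant mode: no rotation, constant gravity
  tr0 <- generate_orientation_trajectory(1, 10, max_tilt = 0.3, mode = "constant")
  expect_equal(max(abs(tr0$gyro)), 0)
  expect_equal(diff(range(tr0$accel[, 3])), 0, tolerance = 1e-12)
  # pure pitch: vertical gravity component follows cos(pitch)
  tr1 <- generate_orientation_trajectory(2, 20, max_tilt = 20 * pi / 180,
                                         mode = "pitch", freq = 0.2)
  pitch <- 20 * pi / 180 * sin(2 * pi * 0.2 * tr1$t)
  expect_equal(tr1$gravity[, 3], cos(pitch), tolerance = 1e-12)
  # random trajectory: brute-force composition of per-sample rotations
  # reproduces the emitted quaternion truth
  tr <- generate_orientation_trajectory(3, 30, mode = "random")
  qhat <- integrate_gyro(tr$gyro, q0 = tr$orientation[1, ])
  err <- geodesic_distance(qhat, tr$orientation)
  expect_lt(max(err), 1e-6)
})
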