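test_that("imu_recording validates its invariants", {
  t <- (0:99) / 100
  m <- matrix(0, 100, 3)
  expect_s3_class(imu_recording(t, m, m, "head"), "imu_recording")
  expect_error(imu_recording(rev(t), m, m, "head"), class = "imu_time_monotone")
  expect_error(imu_recording(t^1.01, m, m, "head"), class = "imu_time_uniform")
  expect_error(imu_recording(t, m[1:50, ], m, "head"), class = "imu_length")
  expect_error(imu_recording(t, m, m, "head", sample_rate = -1),
               class = "imu_rate")
})

test_that("recordings round-trip through files bit-exactly", {
  set.seed(10)
  n <- 500
  rec <- imu_recording((0:(n - 1)) / 100, matrix(rnorm(3 * n), n),
                       matrix(rnorm(3 * n), n), "trunk")
  path <- tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path, "trunk")
  expect_identical(back$accel, rec$accel)
  expect_identical(back$gyro, rec$gyro)
  expect_identical(back$t, rec$t)
  unlink(path)
})

test_that("malformed recording files are rejected with typed errors", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("t,ax,ay", "0,0,0"), path)
  expect_error(read_recording(path, "head"), class = "imu_columns")
  # shuffled timestamps
  set.seed(11)
  n <- 300
  rec <- imu_recording((0:(n - 1)) / 100, matrix(rnorm(3 * n), n),
                       matrix(rnorm(3 * n), n), "head")
  shuffled <- rec
  shuffled$t <- sample(shuffled$t)
  df <- data.frame(t = shuffled$t, shuffled$accel, shuffled$gyro)
  names(df) <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_recording(path, "head"), class = "imu_time_monotone")
  # NaN run longer than 0.5 s
  df2 <- data.frame(t = (0:299) / 100, ax = 0, ay = 0, az = 1,
                    gx = 0, gy = 0, gz = 0)
  df2$ax[100:170] <- NA
  utils::write.csv(df2, path, row.names = FALSE)
  expect_error(read_recording(path, "head"), class = "imu_nan_run")
  expect_error(read_recording(tempfile(), "head"), class = "imu_missing_file")
  unlink(path)
})

test_that("knock detection finds the synchronization spikes and nothing else", {
  ses <- noisy_session()
  kh <- detect_knocks(ses$head)
  kt <- detect_knocks(ses$trunk)
  expect_length(kt, 2L)
  expect_length(kh, 2L)
  expect_lt(max(abs(kt - ses$truth$knock_times)), 0.02)
  # head knocks appear at the mapped device times
  expected_h <- ses$truth$clock_offset +
    (1 + ses$truth$clock_drift) * ses$truth$knock_times
  expect_lt(max(abs(kh - expected_h)), 0.02)
  # constant gravity: no events; threshold above spike amplitude: no events
  quiet <- imu_recording((0:2999) / 100, matrix(rep(c(0, 0, 1), each = 3000), 3000),
                         matrix(0, 3000, 3), "head")
  expect_length(detect_knocks(quiet), 0L)
  expect_length(detect_knocks(ses$trunk, threshold = 50), 0L)
  expect_error(detect_knocks(slice_recording(ses$trunk, 0, 5)),
               class = "imu_too_short")
})

test_that("two-point sync model solves the trunk-to-head time map", {
  s0 <- fit_sync(c(10, 600), c(10, 600))
  expect_equal(s0$offset, 0)
  expect_equal(s0$drift, 0)
  s1 <- fit_sync(c(10.5, 600.5), c(10, 600))
  expect_equal(s1$offset, 0.5)
  expect_equal(s1$drift, 0)
  expect_error(fit_sync(10, c(10, 600)), class = "sync_impossible")
  expect_error(fit_sync(c(10, 10), c(10, 10)), class = "sync_degenerate")

  ses <- noisy_session()
  sync <- fit_sync(detect_knocks(ses$head), detect_knocks(ses$trunk))
  expect_lt(abs(sync$offset - ses$truth$clock_offset), 1e-3)
  expect_lt(abs(sync$drift - ses$truth$clock_drift), 1e-6)
  # involution consistency: head->trunk and trunk->head compose to identity
  rev_sync <- fit_sync(detect_knocks(ses$trunk), detect_knocks(ses$head))
  t <- c(0, 100, 500)
  expect_equal(sync_head_time(rev_sync, sync_head_time(sync, t)), t,
               tolerance = 1e-9)
  expect_equal(sync_trunk_time(sync, sync_head_time(sync, t)), t,
               tolerance = 1e-12)
})

test_that("calibration recovers the mounting rotation", {
  n <- 600
  t <- (0:(n - 1)) / 100
  # already body-aligned: identity
  static <- imu_recording(t, matrix(rep(c(0, 0, 1), each = n), n),
                          matrix(0, n, 3), "trunk")
  nodw <- 0.8 * sin(2 * pi * t)
  nod <- imu_recording(t, matrix(rep(c(0, 0, 1), each = n), n),
                       cbind(0, nodw, 0), "head")
  cal <- fit_calibration(static, nod)
  expect_lt(geodesic_distance(cal$rotation, c(1, 0, 0, 0)), 1e-6)

  # rolled 90 degrees about the AP axis: gravity restored to +z exactly
  q_roll <- quat_from_axis_angle(c(1, 0, 0), pi / 2)
  static_r <- imu_recording(t, quat_rotate(q_roll, static$accel),
                            matrix(0, n, 3), "trunk")
  cal_r <- fit_calibration(static_r)
  g_cal <- colMeans(quat_rotate(cal_r$rotation, static_r$accel))
  expect_equal(g_cal, c(0, 0, 1), tolerance = 1e-12)

  # full synthetic calibration: known arbitrary mounting recovered within 2 deg
  ses <- noisy_session()
  sync <- fit_sync(detect_knocks(ses$head), detect_knocks(ses$trunk))
  sw <- sync_head_time(sync, ses$truth$static_window)
  nw <- sync_head_time(sync, ses$truth$nod_window)
  cal_h <- fit_calibration(slice_recording(ses$head, sw[1], sw[2]),
                           slice_recording(ses$head, nw[1], nw[2]))
  expect_lt(geodesic_distance(cal_h$rotation,
                              quat_conjugate(ses$truth$mounting_head)),
            2 * pi / 180)
  # static residual after calibration is horizontal-free
  cal_t <- fit_calibration(slice_recording(ses$trunk, 2, 6))
  resid <- colMeans(quat_rotate(cal_t$rotation,
                                slice_recording(ses$trunk, 2, 6)$accel))
  expect_lt(max(abs(resid[1:2])), 1e-3)

  # error paths
  moving <- imu_recording(t, matrix(rnorm(3 * n, 0, 1), n), matrix(0, n, 3),
                          "trunk")
  expect_error(fit_calibration(moving), class = "calib_not_static")
  bad_nod <- imu_recording(t, matrix(rep(c(0, 0, 1), each = n), n),
                           cbind(0, 0, nodw), "head")
  expect_error(fit_calibration(static, bad_nod),
               class = "calib_ill_conditioned")
})
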