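# Shared fixtures, generated once per test run and memoized. Sessions are the
# package's own synthetic recordings; nothing is read from disk.

.session_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .session_cache)) {
    assign(key, force(expr), envir = .session_cache)
  }
  get(key, envir = .session_cache)
}

# clean generator settings used when a test needs signal-level access without
# mounting rotation, clock offset or pitch motion in the way
plain_params <- function(...) {
  defaults <- list(accel_noise_sd = 0, gyro_noise_sd = 0, gyro_drift_rate = 0,
                   clock_offset = 0, clock_drift = 0,
                   mounting_head = c(1, 0, 0, 0),
                   mounting_trunk = c(1, 0, 0, 0),
                   pitch_velocity_amp = c(head = 0, trunk = 0),
                   include_cycling = FALSE)
  do.call(gait_params, utils::modifyList(defaults, list(...)))
}

# default-conditions noisy session, 600 s
noisy_session <- function() {
  cached("noisy600", generate_session(gait_params(seed = 42), 600))
}

# noiseless full-featured session (mounting, clock model, pitch), 600 s
noiseless_session <- function() {
  cached("clean600", generate_session(
    gait_params(seed = 7, accel_noise_sd = 0, gyro_noise_sd = 0,
                gyro_drift_rate = 0, include_cycling = FALSE), 600))
}

noiseless_run <- function() {
  cached("clean600run", {
    ses <- noiseless_session()
    run_pipeline(pipeline_config(), head = ses$head, trunk = ses$trunk)
  })
}

noisy_run <- function() {
  cached("noisy600run", {
    ses <- noisy_session()
    run_pipeline(pipeline_config(), head = ses$head, trunk = ses$trunk)
  })
}

# two-hour default-conditions session for the distribution-level checks;
# stability measures are not needed there, only detection and frequencies
long_session <- function() {
  cached("long2h", generate_session(gait_params(seed = 1), 7200))
}

long_run <- function() {
  cached("long2hrun", {
    ses <- long_session()
    run_pipeline(pipeline_config(compute_measures = FALSE),
                 head = ses$head, trunk = ses$trunk)
  })
}

# prefilter a generate_orientation_trajectory() output the way the pipeline
# prefilters recordings (accel low-pass, gyro high-pass)
prefilter_traj <- function(tr, f_lp = 1, fs = 100) {
  rec <- imu_recording(tr$t, tr$accel, tr$gyro, "head", fs)
  out <- prefilter_imu(rec, f_lp)
  list(accel = out$accel, gyro = out$gyro)
}

# brute-force reference: integrate a body-rate series into a quaternion
# trajectory by composing one small rotation per sample
integrate_gyro <- function(gyro, q0 = c(1, 0, 0, 0), dt = 0.01) {
  n <- nrow(gyro)
  q <- matrix(0, n, 4L)
  q[1L, ] <- q0
  for (i in 2:n) {
    w <- gyro[i, ]
    a <- sqrt(sum(w^2)) * dt
    r <- if (a > 0) quat_from_axis_angle(w / sqrt(sum(w^2)), -a) else c(1, 0, 0, 0)
    q[i, ] <- quat_multiply(r, q[i - 1L, ])
  }
  q
}

# tie-free Kruskal-Wallis H computed from first principles
kw_h_oracle <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  sizes <- lengths(groups)
  idx <- split(seq_len(n), rep(seq_along(groups), sizes))
  s <- sum(vapply(idx, function(i) sum(r[i])^2 / length(i), numeric(1)))
  12 / (n * (n + 1)) * s - 3 * (n + 1)
}
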