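#' Parameters of the synthetic dual-IMU gait generator
#'
#' Collects every tunable of [generate_session()] with defaults chosen to
#' mimic free-living gait recordings: step frequencies drawn per bout from a
#' normal distribution centered near the 2 Hz locomotion fundamental, a
#' right-skewed distribution of vertical RMS acceleration with mode near
#' 0.3 g, a heavy-tailed (Zipf-like) distribution of bout lengths, harmonic
#' gait spectra with configurable even/odd balance, per-axis head-vs-trunk
#' attenuation, phase-locked head pitching, gyroscope bias drift, white
#' sensor noise, and a linear clock offset + drift between the two devices.
#'
#' @param step_freq_mean,step_freq_sd mean and SD of per-bout step frequency
#'   draws, Hz
#' @param vertical_rms_mode mode of the per-bout vertical RMS acceleration, g
#' @param rms_lognorm_sd log-scale SD of the per-bout amplitude draw
#'   (lognormal, truncated below at 0.2 g so every step clears the detector)
#' @param n_harmonics number of harmonics per parity in the gait spectrum
#' @param harmonic_decay per-harmonic geometric amplitude ratio (AP and V)
#' @param hr_targets per-axis target harmonic ratios, names `AP`, `ML`, `V`
#' @param ac_targets per-axis attenuation coefficients in `[-1, 1)`, names
#'   `AP`, `ML`, `V`: noiseless head gait acceleration is
#'   `(1 - ac) * trunk` per axis
#' @param axis_rms_ratio RMS of AP and ML trunk acceleration relative to V
#' @param head_pitch_phase target corrected phase between vertical head
#'   displacement and head pitch angle, radians (default -50 degrees)
#' @param trunk_pitch_phase same for trunk pitch (default equal to head)
#' @param pitch_velocity_amp named amplitudes (rad/s) of the head and trunk
#'   pitch-velocity sinusoids during gait
#' @param bout_length_law list with `exponent`, `min`, `max`: discrete
#'   truncated power law (P(L) proportional to L^-exponent) over steps/bout
#' @param within_bout_jitter_sd,within_bout_jitter_tau SD (Hz) and correlation
#'   time (s) of the smooth AR(1) jitter added to the bout base frequency
#' @param gyro_drift_rate constant-rate gyroscope bias growth, rad/s per hour
#' @param accel_noise_sd,gyro_noise_sd white sensor noise SDs (g, rad/s)
#' @param clock_offset,clock_drift head-device clock model:
#'   `head_time = clock_offset + (1 + clock_drift) * trunk_time`
#' @param mounting_head,mounting_trunk unit quaternions rotating body-frame
#'   vectors into each sensor's frame (what the calibration must undo)
#' @param include_cycling embed one cycling segment (non-gait confounder)?
#' @param cycling_duration length of the embedded cycling segment, s
#' @param rest_min,rest_mean_extra rest gaps between bouts are
#'   `rest_min + Exp(rest_mean_extra)` seconds (all gaps > 1.5 s, so true
#'   bout boundaries are unambiguous)
#' @param seed integer RNG seed; identical params + seed give bit-identical
#'   sessions
#' @return validated list of class `gait_params`
#' @export
gait_params <- function(step_freq_mean = 1.86,
                        step_freq_sd = 0.23,
                        vertical_rms_mode = 0.3,
                        rms_lognorm_sd = 0.15,
                        n_harmonics = 10L,
                        harmonic_decay = 0.40,
                        hr_targets = c(AP = 4, ML = 2.5, V = 6),
                        ac_targets = c(AP = 0.3, ML = 0.2, V = 0.05),
                        axis_rms_ratio = c(AP = 0.6, ML = 0.4),
                        head_pitch_phase = -50 * pi / 180,
                        trunk_pitch_phase = NULL,
                        pitch_velocity_amp = c(head = 0.6, trunk = 0.4),
                        bout_length_law = list(exponent = 1.5, min = 2L, max = 2000L),
                        within_bout_jitter_sd = 0.03,
                        within_bout_jitter_tau = 0.5,
                        gyro_drift_rate = 0.05,
                        accel_noise_sd = 0.02,
                        gyro_noise_sd = 0.01,
                        clock_offset = 0.3,
                        clock_drift = 1e-5,
                        mounting_head = quat_from_axis_angle(
                          c(1, 1, 1) / sqrt(3), 15 * pi / 180),
                        mounting_trunk = quat_from_axis_angle(
                          c(1, 0, 0), 8 * pi / 180),
                        include_cycling = TRUE,
                        cycling_duration = 30,
                        rest_min = 2.5,
                        rest_mean_extra = 2.5,
                        seed = 1L) {
  if (is.null(trunk_pitch_phase)) trunk_pitch_phase <- head_pitch_phase
  p <- list(step_freq_mean = step_freq_mean, step_freq_sd = step_freq_sd,
            vertical_rms_mode = vertical_rms_mode,
            rms_lognorm_sd = rms_lognorm_sd,
            n_harmonics = as.integer(n_harmonics),
            harmonic_decay = harmonic_decay, hr_targets = hr_targets,
            ac_targets = ac_targets, axis_rms_ratio = axis_rms_ratio,
            head_pitch_phase = head_pitch_phase,
            trunk_pitch_phase = trunk_pitch_phase,
            pitch_velocity_amp = pitch_velocity_amp,
            bout_length_law = bout_length_law,
            within_bout_jitter_sd = within_bout_jitter_sd,
            within_bout_jitter_tau = within_bout_jitter_tau,
            gyro_drift_rate = gyro_drift_rate,
            accel_noise_sd = accel_noise_sd, gyro_noise_sd = gyro_noise_sd,
            clock_offset = clock_offset, clock_drift = clock_drift,
            mounting_head = mounting_head, mounting_trunk = mounting_trunk,
            include_cycling = include_cycling,
            cycling_duration = cycling_duration,
            rest_min = rest_min, rest_mean_extra = rest_mean_extra,
            seed = as.integer(seed))
  validate_gait_params(p)
  structure(p, class = "gait_params")
}

validate_gait_params <- function(p) {
  stopifnot(p$step_freq_mean > 0, p$step_freq_sd >= 0,
            p$vertical_rms_mode > 0, p$n_harmonics >= 1L,
            p$harmonic_decay > 0, p$harmonic_decay < 1,
            all(p$ac_targets < 1),
            all(c("AP", "ML", "V") %in% names(p$ac_targets)),
            all(c("AP", "ML", "V") %in% names(p$hr_targets)),
            p$within_bout_jitter_sd >= 0, p$gyro_drift_rate >= 0,
            p$accel_noise_sd >= 0, p$gyro_noise_sd >= 0,
            p$bout_length_law$min >= 2, p$bout_length_law$max >= p$bout_length_law$min,
            abs(p$clock_drift) < 1e-3)
  invisible(p)
}

# run code under a temporary RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# truncated discrete power law over steps per bout
sample_bout_length <- function(n, law) {
  k <- law$min:law$max
  if (length(k) == 1L) return(rep.int(k, n))
  pmf <- k^(-law$exponent)
  sample(k, n, replace = TRUE, prob = pmf / sum(pmf))
}

# per-axis harmonic amplitude profiles; even harmonics sit at multiples of the
# step frequency, odd ones at odd multiples of the stride (half-step) frequency
axis_profiles <- function(p) {
  N <- p$n_harmonics
  r <- p$harmonic_decay
  prof <- list()
  for (ax in c("AP", "V")) {
    e <- r^(0:(N - 1L))
    o <- sqrt(1 / p$hr_targets[[ax]]) * e
    prof[[ax]] <- list(even = e, odd = o)
  }
  # ML: monophasic within the stride (odd/stride power dominates in total) but
  # with the single largest bin still at the step frequency so V and ML
  # predominant frequencies agree during walking; the odd profile is spread
  # over several stride harmonics because concentrating it at the stride
  # fundamental would overtake the step-frequency bin
  e <- 0.3^(0:(N - 1L))
  o_shape <- 0.9^(0:(N - 1L))
  b <- sqrt(p$hr_targets[["ML"]] * sum(e^2) / sum(o_shape^2))
  prof$ML <- list(even = e, odd = b * o_shape)
  # unit-profile RMS for scaling to target amplitudes
  for (ax in names(prof)) {
    prof[[ax]]$rms1 <- sqrt(sum(prof[[ax]]$even^2, prof[[ax]]$odd^2) / 2)
  }
  prof
}

# sum of harmonics at step phase phi: even at k*f, odd at (2k-1)*f/2
harmonic_sum <- function(phi, prof, f_nominal, nyquist = 50) {
  out <- numeric(length(phi))
  N <- length(prof$even)
  for (k in seq_len(N)) {
    if (k * f_nominal < nyquist) out <- out + prof$even[k] * cos(k * phi)
    fo <- (2 * k - 1) / 2 * f_nominal
    if (fo < nyquist) out <- out + prof$odd[k] * cos((2 * k - 1) / 2 * phi)
  }
  out
}

# smooth AR(1) frequency jitter, stationary sd `sd`, correlation time tau (s)
ar1_jitter <- function(n, sd, tau, dt) {
  if (sd <= 0 || n == 0L) return(numeric(n))
  rho <- exp(-dt / tau)
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(innov, rho, method = "recursive"))
}

half_sine_pulse <- function(t, t0, width, amp) {
  u <- (t - t0) / width
  ifelse(u >= 0 & u <= 1, amp * sin(pi * u), 0)
}

cosine_ramp <- function(x) {
  # 0 at x<=0, 1 at x>=1, raised-cosine in between
  x <- pmin(1, pmax(0, x))
  0.5 - 0.5 * cos(pi * x)
}

#' Generate a synthetic dual-IMU recording session with ground truth
#'
#' Builds a full recording day in miniature on a common (trunk) clock: a
#' synchronization knock near the start and end, one static and one five-nod
#' calibration segment, then alternating rest and walking bouts (optionally
#' with one cycling segment). Trunk vertical acceleration during gait is a
#' harmonic series at the drawn step frequency whose per-step peaks exceed
#' 0.2 g height and 0.4 g prominence; head channels equal the trunk channels
#' attenuated per axis by the requested attenuation coefficients plus
#' independent sensor noise; head pitch velocity is a sinusoid at the step
#' frequency phase-locked to vertical head acceleration so that the corrected
#' displacement-vs-angle phase equals `head_pitch_phase`. The head device is
#' emitted on its own clock with the configured offset and drift. Device
#' orientation follows the integrated pitch velocity, so gyroscope, gravity
#' and orientation ground truth are mutually consistent.
#'
#' @param params [gait_params()]
#' @param duration session length, seconds (>= 60)
#' @return list with elements `head`, `trunk` ([imu_recording()]s) and
#'   `truth`, a `ground_truth` list containing per-step times/frequencies and
#'   bout ids, bout boundaries, per-sample segment labels, per-device true
#'   orientation (body tilt quaternions) and gravity in sensor coordinates,
#'   the mounting rotations, the clock model, and the calibration windows.
#' @export
generate_session <- function(params, duration) {
  stopifnot(inherits(params, "gait_params"))
  validate_gait_params(params)
  if (duration < 60) {
    stop(imu_error("session_too_short",
                   "duration must be >= 60 s to contain calibration and knocks"))
  }
  with_seed(params$seed, generate_session_impl(params, duration))
}

generate_session_impl <- function(p, duration) {
  fs <- 100
  dt <- 1 / fs
  n <- round(duration * fs)
  t <- (0:(n - 1)) * dt

  knock_times <- c(0.5, duration - 0.55)
  static_win <- c(2, 6)
  nod_win <- c(7, 12)
  act_start <- 14
  act_end <- duration - 1.6

  # ---- schedule bouts, rests and the optional cycling segment -------------
  label <- rep("rest", n)
  rate <- numeric(n)            # instantaneous step-phase rate, rad/s
  amp <- numeric(n)             # per-bout vertical RMS amplitude, g
  bout_id <- rep(NA_integer_, n)
  bouts <- list()
  cyc_win <- NULL
  cursor <- act_start
  b <- 0L
  cycling_pending <- p$include_cycling && duration >= 300
  while (cursor < act_end - 5) {
    if (cycling_pending && cursor >= 0.4 * duration) {
      c0 <- cursor
      c1 <- min(c0 + p$cycling_duration, act_end)
      idx <- which(t >= c0 & t < c1)
      label[idx] <- "cycling"
      cyc_win <- c(c0, c1)
      cycling_pending <- FALSE
      cursor <- c1 + p$rest_min + stats::rexp(1, 1 / p$rest_mean_extra)
      next
    }
    L <- sample_bout_length(1L, p$bout_length_law)
    f_b <- stats::rnorm(1, p$step_freq_mean, p$step_freq_sd)
    f_b <- min(max(f_b, 0.6), 4.5)
    A_b <- p$vertical_rms_mode *
      exp(stats::rnorm(1, p$rms_lognorm_sd^2, p$rms_lognorm_sd))
    # clamp so every weak step clears the detector floor and no gait sample
    # reaches the knock threshold
    A_b <- min(max(A_b, 0.9 * p$vertical_rms_mode), 4 / 3 * p$vertical_rms_mode)
    g0 <- cursor
    g1 <- min(g0 + (L + 1.5) / f_b, act_end)
    idx <- which(t >= g0 & t < g1)
    if (length(idx) < 10L) break
    b <- b + 1L
    jit <- ar1_jitter(length(idx), p$within_bout_jitter_sd,
                      p$within_bout_jitter_tau, dt)
    f_inst <- pmax(0.5, f_b + jit)
    rate[idx] <- 2 * pi * f_inst
    amp[idx] <- A_b
    label[idx] <- "gait"
    bout_id[idx] <- b
    bouts[[b]] <- list(id = b, g0 = g0, g1 = t[idx[length(idx)]] + dt,
                       base_freq = f_b, amp = A_b, planned_steps = L)
    cursor <- g1 + p$rest_min + stats::rexp(1, 1 / p$rest_mean_extra)
  }
  if (!length(bouts)) {
    stop(imu_error("session_no_gait", "session too short to schedule any bout"))
  }

  # fixed-window labels override activity labels (scheduler keeps them clear)
  label[t >= static_win[1] & t < static_win[2]] <- "calibration-static"
  label[t >= nod_win[1] & t < nod_win[2]] <- "calibration-nod"
  for (k in knock_times) label[t >= k - 0.1 & t < k + 0.1] <- "knock"

  # ---- global step phase and per-bout phase-domain envelopes --------------
  phi <- cumsum(rate) * dt
  env <- numeric(n)
  step_time <- numeric(0)
  step_freq <- numeric(0)
  step_bout <- integer(0)
  bout_tab <- data.frame(bout = integer(0), t_first = numeric(0),
                         t_last = numeric(0), n_steps = integer(0),
                         base_freq = numeric(0), amp = numeric(0))
  for (bt in bouts) {
    idx <- which(!is.na(bout_id) & bout_id == bt$id)
    ph <- phi[idx]
    phi_first <- 2 * pi * ceiling((ph[1] + pi) / (2 * pi))
    phi_avail <- 2 * pi * floor((ph[length(ph)] - pi) / (2 * pi))
    n_steps <- max(0, floor((phi_avail - phi_first) / (2 * pi)) + 1)
    n_steps <- min(n_steps, bt$planned_steps)
    # a bout needs at least two steps; degenerate truncations become rest
    if (n_steps < 2) { amp[idx] <- 0; label[idx] <- "rest"; bout_id[idx] <- NA; next }
    phi_last <- phi_first + 2 * pi * (n_steps - 1)
    env[idx] <- cosine_ramp((ph - (phi_first - pi)) / (pi / 2)) *
      cosine_ramp(((phi_last + pi) - ph) / (pi / 2))
    # zero out samples after the envelope has closed (phase keeps running)
    env[idx][ph > phi_last + pi] <- 0
    env[idx][ph < phi_first - pi] <- 0
    kk <- phi_first + 2 * pi * (0:(n_steps - 1))
    st <- stats::approx(ph, t[idx], xout = kk)$y
    sf <- stats::approx(t[idx], rate[idx] / (2 * pi), xout = st)$y
    step_time <- c(step_time, st)
    step_freq <- c(step_freq, sf)
    step_bout <- c(step_bout, rep(bt$id, n_steps))
    bout_tab <- rbind(bout_tab, data.frame(
      bout = bt$id, t_first = st[1], t_last = st[n_steps], n_steps = n_steps,
      base_freq = bt$base_freq, amp = bt$amp))
  }

  prof <- axis_profiles(p)
  rms_scale <- c(AP = unname(p$axis_rms_ratio[["AP"]]),
                 ML = unname(p$axis_rms_ratio[["ML"]]), V = 1)

  nod_rate <- function(tm) {
    # five pitch nods, 1 Hz, forward first, smooth on/off envelope
    inside <- tm >= nod_win[1] & tm <= nod_win[2]
    u <- (tm - nod_win[1])
    amp_env <- cosine_ramp(u / 0.5) * cosine_ramp((nod_win[2] - tm) / 0.5)
    ifelse(inside, 1.0 * amp_env * sin(2 * pi * 1 * u), 0)
  }
  nod_angle <- function(tm) {
    inside <- tm >= nod_win[1] & tm <= nod_win[2]
    u <- (tm - nod_win[1])
    amp_env <- cosine_ramp(u / 0.5) * cosine_ramp((nod_win[2] - tm) / 0.5)
    ifelse(inside, amp_env * (1 - cos(2 * pi * u)) / (2 * pi), 0)
  }

  cyc <- list(cadence = 1.6, pulse_amp = 0.55, pulse_sd = 0.008,
              v_tone_amp = 0.06, ml_freq = 0.8, ml_amp = 0.08, ap_amp = 0.05)
  cycling_world <- function(tm) {
    out <- matrix(0, length(tm), 3L)
    if (is.null(cyc_win)) return(out)
    inside <- tm >= cyc_win[1] & tm <= cyc_win[2]
    if (!any(inside)) return(out)
    u <- tm[inside] - cyc_win[1]
    envc <- cosine_ramp(u / 0.5) * cosine_ramp((cyc_win[2] - tm[inside]) / 0.5)
    per <- 1 / cyc$cadence
    j <- round(u / per - 0.5)
    tj <- (j + 0.5) * per
    pulses <- cyc$pulse_amp * exp(-(u - tj)^2 / (2 * cyc$pulse_sd^2))
    out[inside, 3L] <- envc * (pulses + cyc$v_tone_amp * cos(2 * pi * cyc$cadence * u))
    out[inside, 2L] <- envc * cyc$ml_amp * cos(2 * pi * cyc$ml_freq * u)
    out[inside, 1L] <- envc * cyc$ap_amp * cos(2 * pi * cyc$cadence * u)
    out
  }

  # continuous-time evaluation of the world-frame (aligned) gait signals at
  # arbitrary master-clock times; interpolating the phase (not the signal)
  # keeps the head device's resampled channels free of interpolation loss
  eval_world <- function(tm) {
    ph <- stats::approx(t, phi, xout = tm, rule = 2)$y
    ev <- stats::approx(t, env, xout = tm, rule = 2)$y
    am <- stats::approx(t, amp, xout = tm, rule = 2, method = "constant", f = 0)$y
    fb <- stats::approx(t, ifelse(is.na(bout_id), 0, rate / (2 * pi)),
                        xout = tm, rule = 2, method = "constant", f = 0)$y
    iW <- matrix(0, length(tm), 3L)
    gaitish <- ev > 0 & am > 0
    for (ax in 1:3) {
      axn <- c("AP", "ML", "V")[ax]
      pr <- prof[[axn]]
      s <- numeric(length(tm))
      if (any(gaitish)) {
        s[gaitish] <- harmonic_sum(ph[gaitish], pr, p$step_freq_mean)
      }
      iW[, ax] <- s * ev * am * rms_scale[[axn]] / pr$rms1
    }
    iW <- iW + cycling_world(tm)
    beta_h <- p$head_pitch_phase + pi / 2
    beta_t <- p$trunk_pitch_phase + pi / 2
    # pitch angle is defined analytically (bounded); the emitted pitch rate is
    # the dominant sinusoidal term of its derivative, so gyro and orientation
    # agree everywhere except inside the brief bout on/off ramps
    fb_safe <- pmax(fb, 0.5)
    pitch_head <- ev * p$pitch_velocity_amp[["head"]] * cos(ph + beta_h) +
      nod_rate(tm)
    pitch_trunk <- ev * p$pitch_velocity_amp[["trunk"]] * cos(ph + beta_t)
    theta_head <- ev * p$pitch_velocity_amp[["head"]] *
      sin(ph + beta_h) / (2 * pi * fb_safe) + nod_angle(tm)
    theta_trunk <- ev * p$pitch_velocity_amp[["trunk"]] *
      sin(ph + beta_t) / (2 * pi * fb_safe)
    if (!is.null(cyc_win)) {
      inside <- tm >= cyc_win[1] & tm <= cyc_win[2]
      u <- pmax(0, tm - cyc_win[1])
      wc <- 2 * pi * cyc$cadence
      pitch_head[inside] <- pitch_head[inside] + 0.1 * sin(wc * u)[inside]
      pitch_trunk[inside] <- pitch_trunk[inside] + 0.08 * sin(wc * u)[inside]
      theta_head[inside] <- theta_head[inside] +
        (0.1 / wc) * (1 - cos(wc * u))[inside]
      theta_trunk[inside] <- theta_trunk[inside] +
        (0.08 / wc) * (1 - cos(wc * u))[inside]
    }
    knock <- half_sine_pulse(tm, knock_times[1] - 0.025, 0.05, 3) +
      half_sine_pulse(tm, knock_times[2] - 0.025, 0.05, 3)
    list(iW = iW, pitch_head = pitch_head, pitch_trunk = pitch_trunk,
         theta_head = theta_head, theta_trunk = theta_trunk, knock = knock)
  }

  build_device <- function(tm, placement) {
    w <- eval_world(tm)
    iW <- w$iW
    if (placement == "head") {
      iW <- sweep(iW, 2L, 1 - p$ac_targets[c("AP", "ML", "V")], `*`)
      pitch <- w$pitch_head
      theta <- w$theta_head
      q_mount <- p$mounting_head
    } else {
      pitch <- w$pitch_trunk
      theta <- w$theta_trunk
      q_mount <- p$mounting_trunk
    }
    q_body <- quat_from_axis_angle(
      matrix(c(0, -1, 0), length(tm), 3L, byrow = TRUE), theta)
    g_body <- cbind(-sin(theta), 0, cos(theta))
    i_body <- quat_rotate(q_body, iW)
    a_body <- g_body + i_body
    a_body[, 1L] <- a_body[, 1L] + w$knock
    w_body <- cbind(0, pitch, 0)
    a_s <- quat_rotate(q_mount, a_body)
    w_s <- quat_rotate(q_mount, w_body)
    g_s <- quat_rotate(q_mount, g_body)
    # sensor imperfections
    ndev <- length(tm)
    if (p$accel_noise_sd > 0) {
      a_s <- a_s + matrix(stats::rnorm(3 * ndev, 0, p$accel_noise_sd), ndev, 3L)
    }
    if (p$gyro_noise_sd > 0) {
      w_s <- w_s + matrix(stats::rnorm(3 * ndev, 0, p$gyro_noise_sd), ndev, 3L)
    }
    if (p$gyro_drift_rate > 0) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      w_s <- w_s + outer((p$gyro_drift_rate / 3600) * (tm - tm[1]), u)
    }
    list(accel = a_s, gyro = w_s, q_body = q_body, g_sensor = g_s)
  }

  trunk_dev <- build_device(t, "trunk")
  # head device samples its own uniform clock; those ticks correspond to
  # earlier/later master times through the linear clock model
  t_master_of_head <- (t - p$clock_offset) / (1 + p$clock_drift)
  head_dev <- build_device(t_master_of_head, "head")

  head <- imu_recording(t, head_dev$accel, head_dev$gyro, "head", fs)
  trunk <- imu_recording(t, trunk_dev$accel, trunk_dev$gyro, "trunk", fs)

  segments <- label_runs(t, label, dt)
  truth <- structure(list(
    step_times = step_time, step_freqs = step_freq, step_bouts = step_bout,
    bouts = bout_tab, segments = segments, labels = label,
    orientation_head = head_dev$q_body, orientation_trunk = trunk_dev$q_body,
    gravity_head = head_dev$g_sensor, gravity_trunk = trunk_dev$g_sensor,
    mounting_head = p$mounting_head, mounting_trunk = p$mounting_trunk,
    clock_offset = p$clock_offset, clock_drift = p$clock_drift,
    knock_times = knock_times, static_window = static_win,
    nod_window = nod_win, cycling_window = cyc_win,
    ac_targets = p$ac_targets, head_pitch_phase = p$head_pitch_phase,
    params = p), class = "ground_truth")
  list(head = head, trunk = trunk, truth = truth)
}

label_runs <- function(t, label, dt) {
  r <- rle(label)
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  data.frame(start = t[starts], end = t[ends] + dt, label = r$values,
             stringsAsFactors = FALSE)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d steps in %d bouts, %d segments\n",
              length(x$step_times), nrow(x$bouts), nrow(x$segments)))
  invisible(x)
}

#' Synthetic orientation trajectory for filter validation
#'
#' Generates a ground-truth orientation time series together with the exact
#' body-frame angular velocity and the gravity-plus-transients accelerometer
#' signal a sensor following it would record. Trajectories are yaw-free tilts
#' (the family of orientations the gravity filter estimates). The emitted
#' gyroscope sample at index `i` is the constant body rate that carries the
#' orientation from sample `i - 1` to `i`, so integrating the gyro reproduces
#' the quaternion series to numerical precision.
#'
#' @param seed RNG seed
#' @param duration seconds (at 100 Hz)
#' @param max_tilt maximum tilt angle, rad (< pi/2)
#' @param rate target RMS angular speed, rad/s (`mode = "random"`), or ignored
#'   for the deterministic modes
#' @param mode `"random"` (smooth band-limited random tilt), `"pitch"` (pure
#'   pitch oscillation of amplitude `max_tilt` at `freq` Hz), or `"constant"`
#' @param freq oscillation frequency for `mode = "pitch"`, Hz
#' @param accel_noise_sd white accelerometer noise, g
#' @param transient_sd RMS of band-limited inertial transients added to the
#'   accelerometer, g
#' @param fs sampling rate, Hz
#' @return list with `t`, `accel`, `gyro`, `orientation` (n x 4 quaternions,
#'   same convention as [gravity_filter()]), and `gravity` (true gravity
#'   direction in sensor coordinates)
#' @export
generate_orientation_trajectory <- function(seed, duration, max_tilt = 20 * pi / 180,
                                            rate = 0.5,
                                            mode = c("random", "pitch", "constant"),
                                            freq = 0.2, accel_noise_sd = 0,
                                            transient_sd = 0, fs = 100) {
  mode <- match.arg(mode)
  stopifnot(max_tilt < pi / 2, duration > 1)
  with_seed(seed, {
    n <- round(duration * fs)
    t <- (0:(n - 1)) / fs
    if (mode == "constant") {
      rho <- cbind(rep(max_tilt, n), 0)
    } else if (mode == "pitch") {
      rho <- cbind(max_tilt * sin(2 * pi * freq * t), 0)
    } else {
      bw <- signal::butter(4, 2.5 / (fs / 2), type = "low")
      rho <- cbind(signal::filtfilt(bw, stats::rnorm(n)),
                   signal::filtfilt(bw, stats::rnorm(n)))
      rho <- sweep(rho, 2L, colMeans(rho))
      # scale to the requested RMS angular speed, then honor the tilt bound
      spd <- sqrt(mean(rowSums(apply(rho, 2L, function(c) diff(c) * fs)^2)))
      if (spd > 0) rho <- rho * (rate / spd)
      mt <- max(sqrt(rowSums(rho^2)))
      if (mt > 0.95 * max_tilt) rho <- rho * (0.95 * max_tilt / mt)
    }
    ang <- sqrt(rowSums(rho^2))
    axis <- cbind(ifelse(ang > 1e-12, rho[, 1] / ang, 1),
                  ifelse(ang > 1e-12, rho[, 2] / ang, 0), 0)
    # tilt about the axis perpendicular to the tilt direction: rotate the
    # tilt vector (rx, ry) by +90 deg to get the horizontal rotation axis
    axis <- cbind(-axis[, 2], axis[, 1], 0)
    q <- quat_from_axis_angle(axis, ang)
    if (is.null(dim(q))) q <- matrix(q, 1L)
    g_s <- quat_rotate(q, matrix(c(0, 0, 1), n, 3L, byrow = TRUE))
    # body rate carrying q[i-1] to q[i]
    gyro <- matrix(0, n, 3L)
    if (n > 1L) {
      r <- quat_multiply(q[-n, , drop = FALSE], quat_conjugate(q[-1L, , drop = FALSE]))
      sw <- sign(r[, 1L]); sw[sw == 0] <- 1
      r <- r * sw
      s <- sqrt(rowSums(r[, 2:4, drop = FALSE]^2))
      angr <- 2 * atan2(s, r[, 1L])
      ax <- r[, 2:4, drop = FALSE] / ifelse(s > 1e-15, s, 1)
      gyro[-1L, ] <- ax * angr * fs
      gyro[s <= 1e-15, ] <- 0
    }
    accel <- g_s
    if (transient_sd > 0) {
      bw2 <- signal::butter(4, 2.5 / (fs / 2), type = "low")
      tr <- apply(matrix(stats::rnorm(3 * n), n, 3L), 2L,
                  function(cc) signal::filtfilt(bw2, cc))
      tr <- tr * (transient_sd / stats::sd(as.vector(tr)))
      accel <- accel + tr
    }
    if (accel_noise_sd > 0) {
      accel <- accel + matrix(stats::rnorm(3 * n, 0, accel_noise_sd), n, 3L)
    }
    list(t = t, accel = accel, gyro = gyro, orientation = q, gravity = g_s)
  })
}

#' Synthetic cycling-like acceleration segment
#'
#' Produces the non-gait confounder the cycling exclusion targets: narrow
#' vertical pulses at the pedaling cadence that trip the step peak detector,
#' but with low vertical RMS and a medial/lateral predominant frequency far
#' from the vertical one — the two features the cycling classifier keys on.
#'
#' @param duration seconds
#' @param cadence pedal cadence, Hz
#' @param fs sampling rate, Hz
#' @return list with `t` and `accel`, an `n x 3` matrix of aligned-frame
#'   inertial acceleration with columns AP, ML, V (g)
#' @export
generate_cycling_segment <- function(duration, cadence = 1.6, fs = 100) {
  stopifnot(duration > 0)
  n <- round(duration * fs)
  t <- (0:(n - 1)) / fs
  per <- 1 / cadence
  j <- round(t / per - 0.5)
  tj <- (j + 0.5) * per
  v <- 0.55 * exp(-(t - tj)^2 / (2 * 0.008^2)) + 0.06 * cos(2 * pi * cadence * t)
  ml <- 0.08 * cos(2 * pi * 0.8 * t)
  ap <- 0.05 * cos(2 * pi * cadence * t)
  list(t = t, accel = cbind(ap, ml, v))
}

#' Write / read the ground-truth sidecar file
#'
#' Persists the labeled-segment table, the per-step truth, and the scalar
#' session parameters (clock model, attenuation targets, calibration windows,
#' mounting rotations) as a single delimited text file with one record per
#' row. Per-sample series (orientation, gravity) are not serialized; they are
#' available from the in-memory `ground_truth` object.
#'
#' @param truth `ground_truth` from [generate_session()]
#' @param path file path
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` a list with `segments`, `steps`, and `params`.
#' @export
write_ground_truth <- function(truth, path) {
  seg <- data.frame(kind = "segment", label = truth$segments$label,
                    t0 = truth$segments$start, t1 = truth$segments$end,
                    value = NA_real_)
  stp <- data.frame(kind = "step", label = as.character(truth$step_bouts),
                    t0 = truth$step_times, t1 = NA_real_,
                    value = truth$step_freqs)
  par_num <- c(clock_offset = truth$clock_offset,
               clock_drift = truth$clock_drift,
               head_pitch_phase = truth$head_pitch_phase,
               ac_AP = unname(truth$ac_targets[["AP"]]),
               ac_ML = unname(truth$ac_targets[["ML"]]),
               ac_V = unname(truth$ac_targets[["V"]]),
               static_t0 = truth$static_window[1],
               static_t1 = truth$static_window[2],
               nod_t0 = truth$nod_window[1], nod_t1 = truth$nod_window[2],
               stats::setNames(truth$mounting_head, paste0("mount_head_", c("w", "x", "y", "z"))),
               stats::setNames(truth$mounting_trunk, paste0("mount_trunk_", c("w", "x", "y", "z"))))
  par <- data.frame(kind = "param", label = names(par_num), t0 = NA_real_,
                    t1 = NA_real_, value = unname(par_num))
  out <- rbind(seg, stp, par)
  out$t0 <- sprintf("%.17g", out$t0); out$t1 <- sprintf("%.17g", out$t1)
  out$value <- sprintf("%.17g", out$value)
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  dt <- data.table::fread(path, na.strings = c("NA", "nan"))
  segments <- dt[dt$kind == "segment", ]
  steps <- dt[dt$kind == "step", ]
  params <- dt[dt$kind == "param", ]
  list(segments = data.frame(start = segments$t0, end = segments$t1,
                             label = segments$label),
       steps = data.frame(time = steps$t0, freq = steps$value,
                          bout = as.integer(steps$label)),
       params = stats::setNames(params$value, params$label))
}
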