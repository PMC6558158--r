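#' Pre-filter IMU channels for gravity estimation
#'
#' The gyroscope is high-passed at 0.1 Hz to remove bias drift and the
#' accelerometer is low-passed at `f_lp` to suppress transient (inertial)
#' accelerations, both with 5th-order Butterworth filters applied
#' forward-backward (zero phase; the pipeline is offline).
#'
#' @param rec [imu_recording()]
#' @param f_lp accelerometer low-pass cut-off, Hz; must lie in
#'   (0.1, Nyquist)
#' @return the recording with filtered `accel` and `gyro`
#' @export
prefilter_imu <- function(rec, f_lp = 1) {
  fs <- rec$sample_rate
  if (!(f_lp > 0.1 && f_lp < fs / 2)) {
    stop(imu_error("orientation_flp_range",
                   sprintf("f_lp must be in (0.1, %g) Hz", fs / 2)))
  }
  bh <- signal::butter(5, 0.1 / (fs / 2), type = "high")
  bl <- signal::butter(5, f_lp / (fs / 2), type = "low")
  rec$gyro <- apply(rec$gyro, 2L, function(x)
    filtfilt_padded(bh, x, pad = round(3 * fs / 0.1)))
  rec$accel <- apply(rec$accel, 2L, function(x)
    filtfilt_padded(bl, x, pad = round(3 * fs / f_lp)))
  rec
}

# zero-phase filtering with odd-reflection end padding, so that edge
# transients of the low cut-off filters do not leak into the estimates
filtfilt_padded <- function(filt, x, pad) {
  n <- length(x)
  p <- min(pad, n - 1L)
  xp <- c(2 * x[1L] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  y <- signal::filtfilt(filt, xp)
  y[(p + 1L):(p + n)]
}

#' Per-sample gravity direction and tilt orientation
#'
#' Complementary sensor-fusion filter. Starting from `g(0) = g_world`, each
#' step (i) propagates the previous gravity estimate by the incremental
#' rotation of the gyroscope sample (the exact rotation of `g(t-1)` about the
#' measured axis by `-|omega| dt`, since a world-fixed vector observed from a
#' frame rotating with right-handed body rate omega evolves as
#' `dg/dt = -omega x g`), (ii) blends it with the low-passed accelerometer
#' direction with weight `1 - alpha`, (iii) normalizes, and (iv) builds the
#' orientation quaternion `q(t)` as the minimal rotation taking the world
#' vertical onto `g(t)` (axis `g_world x g(t)`), which by construction never
#' contains yaw. If the estimate becomes antiparallel to the world vertical,
#' the previous quaternion is kept and the event is counted.
#'
#' @param accel `n x 3` low-passed acceleration, g (see [prefilter_imu()])
#' @param gyro `n x 3` high-passed angular velocity, rad/s
#' @param alpha correction factor in `[0, 1]`: 1 = gyro only, 0 = follow the
#'   accelerometer direction exactly
#' @param g_world world gravity direction (unit, default `c(0, 0, 1)`)
#' @param dt sample interval, s
#' @return object of class `orientation_estimate` with fields `gravity`
#'   (`n x 3` unit vectors, sensor coordinates), `orientation` (`n x 4`
#'   quaternions; rotating a sensor-frame vector by `q(t)^-1` expresses it in
#'   the gravity-aligned frame), `alpha`, `g_world`, and `n_degenerate`
#' @export
gravity_filter <- function(accel, gyro, alpha = 0.998, g_world = c(0, 0, 1),
                           dt = 0.01) {
  if (!(alpha >= 0 && alpha <= 1)) {
    stop(imu_error("orientation_alpha_range", "alpha must lie in [0, 1]"))
  }
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  n <- nrow(accel)
  stopifnot(nrow(gyro) == n, ncol(accel) == 3L, ncol(gyro) == 3L)
  g_world <- g_world / sqrt(sum(g_world^2))
  gravity <- matrix(0, n, 3L)
  g <- g_world
  wmag <- sqrt(rowSums(gyro^2))
  theta <- wmag * dt
  ct <- cos(theta); st <- sin(theta)
  n_degenerate <- 0L
  for (i in seq_len(n)) {
    if (theta[i] > 1e-12) {
      u <- gyro[i, ] / wmag[i]
      # rotate g by -theta about u (Rodrigues)
      uxg <- c(u[2] * g[3] - u[3] * g[2],
               u[3] * g[1] - u[1] * g[3],
               u[1] * g[2] - u[2] * g[1])
      g <- g * ct[i] - uxg * st[i] + u * sum(u * g) * (1 - ct[i])
    }
    g <- alpha * g + (1 - alpha) * accel[i, ]
    nrm <- sqrt(sum(g^2))
    if (nrm < 1e-12) { # pathological; keep direction of previous estimate
      g <- gravity[max(i - 1L, 1L), ]
      if (i == 1L) g <- g_world
      nrm <- 1
      n_degenerate <- n_degenerate + 1L
    }
    g <- g / nrm
    gravity[i, ] <- g
  }
  # orientation from gravity: minimal rotation g_world -> g(t)
  q <- tilt_quaternion(gravity, g_world)
  if (is.null(dim(q))) q <- matrix(q, 1L)
  # antiparallel gravity: axis undefined; fall back to previous quaternion
  dots <- gravity %*% g_world
  bad <- which(dots < -1 + 1e-12)
  if (length(bad)) {
    n_degenerate <- n_degenerate + length(bad)
    for (i in bad) q[i, ] <- if (i > 1L) q[i - 1L, ] else c(1, 0, 0, 0)
  }
  structure(list(gravity = gravity, orientation = q, alpha = alpha,
                 g_world = g_world, dt = dt, n_degenerate = n_degenerate),
            class = "orientation_estimate")
}

#' @export
print.orientation_estimate <- function(x, ...) {
  cat(sprintf("<orientation_estimate> n=%d  alpha=%g  degenerate=%d\n",
              nrow(x$gravity), x$alpha, x$n_degenerate))
  invisible(x)
}

#' Transform raw acceleration into the gravity-aligned frame
#'
#' Subtracts the estimated gravity from the raw (unfiltered) acceleration and
#' rotates the residual into the aligned frame, `i_A(t) = rot(q(t)^-1,
#' a(t) - g(t))`. The aligned frame is right-handed with the vertical axis up
#' along gravity, AP forward and ML to the left of the motion direction; it
#' stays body-fixed in yaw because `q(t)` carries no yaw component. Angular
#' velocity is *not* rotated: rotations are reported in the body frame, so the
#' pitch rate is the ML-axis component of the calibrated gyroscope.
#'
#' @param accel_raw `n x 3` raw acceleration in (calibrated) sensor
#'   coordinates, g
#' @param estimate `orientation_estimate` covering every sample
#' @param gyro_body optional `n x 3` body-frame angular velocity to carry
#'   through, rad/s
#' @return object of class `aligned_signals`: `inertial` (`n x 3`, columns
#'   AP, ML, V, g) and `gyro_body` (or `NULL`)
#' @export
to_aligned <- function(accel_raw, estimate, gyro_body = NULL) {
  accel_raw <- as.matrix(accel_raw)
  if (nrow(accel_raw) != nrow(estimate$gravity)) {
    stop(imu_error("orientation_length_mismatch",
                   "estimate does not cover every acceleration sample"))
  }
  iA <- quat_rotate(quat_conjugate(estimate$orientation),
                    accel_raw - estimate$gravity)
  if (is.null(dim(iA))) iA <- matrix(iA, 1L)
  colnames(iA) <- c("AP", "ML", "V")
  structure(list(inertial = iA, gyro_body = gyro_body),
            class = "aligned_signals")
}

#' Export aligned signals as delimited text
#'
#' Columns `t, iA_AP, iA_ML, iA_V, w_roll, w_pitch, w_yaw` (seconds, g,
#' rad/s). Body-frame angular velocity columns are zero-filled when the
#' aligned object carries no gyroscope.
#'
#' @param aligned `aligned_signals`
#' @param timestamps sample times, s
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_aligned <- function(aligned, timestamps, path) {
  gb <- aligned$gyro_body
  if (is.null(gb)) gb <- matrix(0, nrow(aligned$inertial), 3L)
  df <- data.frame(t = timestamps, iA_AP = aligned$inertial[, "AP"],
                   iA_ML = aligned$inertial[, "ML"],
                   iA_V = aligned$inertial[, "V"],
                   w_roll = gb[, 1L], w_pitch = gb[, 2L], w_yaw = gb[, 3L])
  data.table::fwrite(df, path)
  invisible(path)
}

#' @export
print.aligned_signals <- function(x, ...) {
  cat(sprintf("<aligned_signals> n=%d  V RMS=%.3f g\n",
              nrow(x$inertial), sqrt(mean(x$inertial[, "V"]^2))))
  invisible(x)
}
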