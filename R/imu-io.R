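#' IMU recording container
#'
#' Bundles a tri-axial accelerometer + gyroscope time series from one
#' body-worn device. Acceleration is specific force in g (so a device at rest
#' measures +1 g along the upward axis), angular velocity is right-handed body
#' rate in rad/s. Timestamps must be uniform; recordings with gaps or
#' non-monotone time are rejected rather than repaired.
#'
#' @param timestamps numeric vector, seconds from recording start, uniformly
#'   spaced at `1/sample_rate`
#' @param accel `n x 3` matrix, g
#' @param gyro `n x 3` matrix, rad/s
#' @param placement `"head"` or `"trunk"`
#' @param sample_rate sampling rate, Hz (default 100)
#' @return object of class `imu_recording` with fields `t`, `accel`, `gyro`,
#'   `placement`, `sample_rate`
#' @export
imu_recording <- function(timestamps, accel, gyro, placement = c("head", "trunk"),
                          sample_rate = 100) {
  placement <- match.arg(placement)
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  n <- length(timestamps)
  if (ncol(accel) != 3L || ncol(gyro) != 3L) {
    stop(imu_error("imu_columns", "accel and gyro must have three columns"))
  }
  if (nrow(accel) != n || nrow(gyro) != n) {
    stop(imu_error("imu_length", "channel lengths differ from timestamp length"))
  }
  if (!(is.numeric(sample_rate) && sample_rate > 0)) {
    stop(imu_error("imu_rate", "sample_rate must be positive"))
  }
  if (n >= 2L) {
    dt <- diff(timestamps)
    if (any(dt <= 0)) {
      stop(imu_error("imu_time_monotone", "timestamps must be strictly increasing"))
    }
    if (max(abs(dt - 1 / sample_rate)) > 1e-6) {
      stop(imu_error("imu_time_uniform",
                     "timestamps must be uniform at 1/sample_rate within 1e-6 s"))
    }
  }
  structure(list(t = as.numeric(timestamps), accel = unname(accel),
                 gyro = unname(gyro), placement = placement,
                 sample_rate = sample_rate),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> placement=%s  n=%d  fs=%g Hz  duration=%.1f s\n",
              x$placement, length(x$t), x$sample_rate,
              if (length(x$t)) diff(range(x$t)) else 0))
  invisible(x)
}

#' Extract a time slice of a recording
#'
#' @param rec `imu_recording`
#' @param from,to window bounds in seconds (inclusive)
#' @return `imu_recording` restricted to the window
#' @export
slice_recording <- function(rec, from, to) {
  keep <- rec$t >= from & rec$t <= to
  structure(list(t = rec$t[keep], accel = rec$accel[keep, , drop = FALSE],
                 gyro = rec$gyro[keep, , drop = FALSE],
                 placement = rec$placement, sample_rate = rec$sample_rate),
            class = "imu_recording")
}

imu_error <- function(class, message) {
  errorCondition(message, class = c(class, "headstab_error"))
}

#' Read / write delimited IMU time series
#'
#' Files are comma-separated with a header line and columns
#' `t, ax, ay, az, gx, gy, gz` (time in seconds, acceleration in g, angular
#' velocity in rad/s). Values are written with 17 significant digits so a
#' write/read cycle is bit-exact. Non-uniform sampling is rejected, not
#' resampled; runs of non-finite samples longer than 0.5 s are rejected.
#'
#' @param path file path
#' @param placement `"head"` or `"trunk"`
#' @return `read_recording()` returns an [imu_recording()];
#'   `write_recording()` returns `path` invisibly.
#' @export
read_recording <- function(path, placement = c("head", "trunk")) {
  placement <- match.arg(placement)
  if (!file.exists(path)) stop(imu_error("imu_missing_file", paste("no such file:", path)))
  dt <- data.table::fread(path)
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(dt))) {
    stop(imu_error("imu_columns",
                   paste("missing columns:", paste(setdiff(need, names(dt)), collapse = ", "))))
  }
  m <- as.matrix(dt[, need[-1], with = FALSE])
  tvec <- dt$t
  if (any(diff(tvec) <= 0)) {
    stop(imu_error("imu_time_monotone", "timestamps must be strictly increasing"))
  }
  bad <- !stats::complete.cases(m) | !is.finite(tvec)
  if (any(bad)) {
    r <- rle(bad)
    fs_guess <- 1 / stats::median(diff(tvec), na.rm = TRUE)
    if (max(r$lengths[r$values]) > 0.5 * fs_guess) {
      stop(imu_error("imu_nan_run", "run of non-finite samples longer than 0.5 s"))
    }
  }
  fs <- round(1 / stats::median(diff(tvec)))
  imu_recording(tvec, m[, 1:3], m[, 4:6], placement, sample_rate = fs)
}

#' @rdname read_recording
#' @param rec `imu_recording`
#' @export
write_recording <- function(rec, path) {
  m <- cbind(rec$t, rec$accel, rec$gyro)
  ch <- apply(m, 2L, function(col) sprintf("%.17g", col))
  dt <- data.table::as.data.table(ch)
  data.table::setnames(dt, c("t", "ax", "ay", "az", "gx", "gy", "gz"))
  data.table::fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' Detect synchronization knocks
#'
#' Knocking the two devices against each other produces large, brief spikes in
#' acceleration magnitude on both. Returns the times of acceleration-magnitude
#' excursions above `threshold`, separated by at least `refractory` seconds.
#' Each event time is the three-point parabolic interpolation of the magnitude
#' peak within the excursion, which locates a symmetric spike with sub-sample
#' precision — the clock-drift fit over a long baseline needs better than
#' one-sample timing. The first and last event are used for synchronization.
#'
#' @param rec `imu_recording` of at least 10 s
#' @param threshold magnitude threshold, g (default 2.5)
#' @param refractory minimum separation between events, s (default 1)
#' @return numeric vector of event times, possibly empty
#' @export
detect_knocks <- function(rec, threshold = 2.5, refractory = 1) {
  if (diff(range(rec$t)) < 10) {
    stop(imu_error("imu_too_short", "recording must span at least 10 s"))
  }
  mag <- sqrt(rowSums(rec$accel^2))
  above <- which(mag > threshold)
  if (!length(above)) return(numeric(0))
  events <- numeric(0)
  i <- 1L
  while (i <= length(above)) {
    j <- above[i]
    burst <- above[above >= j & rec$t[above] < rec$t[j] + refractory]
    pk <- burst[which.max(mag[burst])]
    frac <- parabolic_peak(mag, pk)
    events <- c(events, rec$t[1L] + (frac - 1) / rec$sample_rate)
    i <- match(TRUE, rec$t[above] >= rec$t[j] + refractory)
    if (is.na(i)) break
  }
  events
}

#' Two-point clock synchronization model
#'
#' The two devices run on independent clocks. With knock events at the start
#' and end of the session, the trunk-to-head time map is modeled as linear:
#' `head_time = offset + (1 + drift) * trunk_time`. `fit_sync()` solves the
#' two-point system exactly; `sync_head_time()` / `sync_trunk_time()` apply
#' the map and its inverse.
#'
#' @param head_knocks,trunk_knocks event times from [detect_knocks()]; the
#'   first and last of each are used and must match one-to-one
#' @return `fit_sync()` returns an object of class `sync_model` with fields
#'   `offset` (s) and `drift` (s/s)
#' @export
fit_sync <- function(head_knocks, trunk_knocks) {
  if (length(head_knocks) < 2L || length(trunk_knocks) < 2L) {
    stop(imu_error("sync_impossible", "need at least two knock events per device"))
  }
  h <- c(head_knocks[1L], head_knocks[length(head_knocks)])
  tt <- c(trunk_knocks[1L], trunk_knocks[length(trunk_knocks)])
  if (abs(diff(tt)) < 1e-9 || abs(diff(h)) < 1e-9) {
    stop(imu_error("sync_degenerate", "coincident knock times; cannot fit drift"))
  }
  slope <- diff(h) / diff(tt)
  drift <- slope - 1
  offset <- h[1L] - slope * tt[1L]
  if (abs(drift) >= 1e-3) {
    stop(imu_error("sync_drift_range",
                   sprintf("fitted clock drift %.2g implausibly large", drift)))
  }
  structure(list(offset = offset, drift = drift), class = "sync_model")
}

#' @rdname fit_sync
#' @param sync `sync_model`
#' @param t times, s
#' @export
sync_head_time <- function(sync, t) sync$offset + (1 + sync$drift) * t

#' @rdname fit_sync
#' @export
sync_trunk_time <- function(sync, t) (t - sync$offset) / (1 + sync$drift)

#' @export
print.sync_model <- function(x, ...) {
  cat(sprintf("<sync_model> offset=%.4f s  drift=%.3g s/s\n", x$offset, x$drift))
  invisible(x)
}

#' Sensor-to-body calibration from static and nodding postures
#'
#' A static posture pins the body-frame vertical (gravity must be purely
#' vertical after calibration); five pitch nods pin the medial/lateral axis
#' (angular velocity purely about ML). The ML axis is estimated as the first
#' principal axis of the nod-segment angular-velocity samples, with its sign
#' chosen so the initial nod is a forward pitch (positive rotation about the
#' leftward ML axis takes the upward axis toward the forward axis). The trunk
#' device is calibrated with the static posture only, in which case the
#' rotation is the minimal (yaw-free) tilt aligning gravity.
#'
#' Body frame convention: right-handed, x = anterior (forward), y = ML (left),
#' z = vertical (up); a static sensor measures +1 g along +z after calibration.
#'
#' @param static_segment `imu_recording` slice (>= 2 s) of quasi-static data;
#'   mean acceleration magnitude must be within 5% of 1 g
#' @param nod_segment optional `imu_recording` slice containing the pitch nods
#' @return object of class `calibration_transform` with field `rotation`, a
#'   unit quaternion: `quat_rotate(rotation, v_sensor)` expresses a
#'   sensor-frame vector in body-frame coordinates
#' @export
fit_calibration <- function(static_segment, nod_segment = NULL) {
  if (diff(range(static_segment$t)) < 2) {
    stop(imu_error("calib_static_short", "static segment must span at least 2 s"))
  }
  g_mean <- colMeans(static_segment$accel)
  g_norm <- sqrt(sum(g_mean^2))
  if (abs(g_norm - 1) > 0.05) {
    stop(imu_error("calib_not_static",
                   sprintf("static segment mean |a| = %.3f g, not within 5%% of 1 g", g_norm)))
  }
  g_hat <- g_mean / g_norm
  if (is.null(nod_segment)) {
    # vertical-only: minimal rotation taking measured gravity to +z, no yaw
    q <- quat_conjugate(tilt_quaternion(g_hat))
    return(structure(list(rotation = quat_normalize(q)),
                     class = "calibration_transform"))
  }
  w <- nod_segment$gyro
  pc <- eigen(crossprod(sweep(w, 2L, colMeans(w))), symmetric = TRUE)
  u <- pc$vectors[, 1L]
  if (abs(sum(u * g_hat)) > 0.9) {
    stop(imu_error("calib_ill_conditioned",
                   "nod rotation axis nearly parallel to gravity"))
  }
  # sign: the first strong nod sample should be a positive (forward) pitch
  p <- as.vector(w %*% u)
  k <- which(abs(p) > 0.5 * max(abs(p)))[1L]
  if (p[k] < 0) u <- -u
  z_b <- g_hat
  y_b <- u - sum(u * z_b) * z_b
  y_b <- y_b / sqrt(sum(y_b^2))
  x_b <- c(y_b[2L] * z_b[3L] - y_b[3L] * z_b[2L],
           y_b[3L] * z_b[1L] - y_b[1L] * z_b[3L],
           y_b[1L] * z_b[2L] - y_b[2L] * z_b[1L])
  R <- rbind(x_b, y_b, z_b) # rows: body axes in sensor coords; maps sensor -> body
  structure(list(rotation = rotmat_to_quat(R)), class = "calibration_transform")
}

#' @rdname fit_calibration
#' @param rec `imu_recording`
#' @param cal `calibration_transform`
#' @return `apply_calibration()` returns the recording with both channels
#'   rotated into the body frame.
#' @export
apply_calibration <- function(rec, cal) {
  rec$accel <- quat_rotate(cal$rotation, rec$accel)
  rec$gyro <- quat_rotate(cal$rotation, rec$gyro)
  rec
}

#' @export
print.calibration_transform <- function(x, ...) {
  ang <- quat_angle(x$rotation) * 180 / pi
  cat(sprintf("<calibration_transform> rotation angle %.2f deg\n", ang))
  invisible(x)
}

# Shepperd's method, rotation matrix (rows = new-frame axes) -> quaternion
rotmat_to_quat <- function(R) {
  # quaternion q with quat_rotate(q, v) == R %*% v
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, s / 4)
  }
  quat_normalize(q)
}
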