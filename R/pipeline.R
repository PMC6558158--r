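#' Pipeline configuration
#'
#' All tunables of the end-to-end analysis in one validated list. Every entry
#' has a documented default; paths may be omitted when recordings are passed
#' to [run_pipeline()] directly.
#'
#' @param head_path,trunk_path optional recording file paths
#' @param out_dir optional output directory for the step table, bout table,
#'   summaries and run log
#' @param alpha gravity-filter correction factor in `[0, 1]`
#' @param f_lp accelerometer low-pass cut-off for gravity estimation, Hz
#' @param knock_threshold,knock_refractory knock detection, g and s
#' @param static_window,nod_window calibration windows, trunk-clock seconds
#' @param min_height,min_prominence,min_distance step detector thresholds
#'   (g, g, s)
#' @param cycling_rms_threshold,cycling_freq_mismatch cycling exclusion
#'   thresholds (g, Hz)
#' @param gate analysis band for head vertical predominant frequency, Hz
#' @param seglen_analysis,seglen_classify spectral segment lengths, samples
#' @param n_harmonics harmonics per parity for the harmonic ratio
#' @param hr_cap harmonic-ratio cap for zero denominators
#' @param max_gap maximum inter-step gap within a bout, s
#' @param compute_measures compute the four stability measures? Disabling
#'   stops the pipeline after the frequency gate (useful for long sessions
#'   where only detection and frequency statistics are needed)
#' @return validated list of class `pipeline_config`
#' @export
pipeline_config <- function(head_path = NULL, trunk_path = NULL, out_dir = NULL,
                            alpha = 0.998, f_lp = 1,
                            knock_threshold = 2.5, knock_refractory = 1,
                            static_window = c(2, 6), nod_window = c(7, 12),
                            min_height = 0.2, min_prominence = 0.4,
                            min_distance = 0.2,
                            cycling_rms_threshold = 0.1,
                            cycling_freq_mismatch = 0.5,
                            gate = c(1, 2.6),
                            seglen_analysis = 512L, seglen_classify = 1024L,
                            n_harmonics = 10L, hr_cap = 100,
                            max_gap = 1.0, compute_measures = TRUE) {
  cfg <- as.list(environment())
  if (!(length(gate) == 2L && gate[2] > gate[1] && gate[1] > 0)) {
    stop(imu_error("config_invalid", "gate must be c(low, high) with high > low > 0"))
  }
  if (!(alpha >= 0 && alpha <= 1)) {
    stop(imu_error("config_invalid", "alpha must lie in [0, 1]"))
  }
  if (!(f_lp > 0.1)) stop(imu_error("config_invalid", "f_lp must exceed 0.1 Hz"))
  if (!(min_distance > 0 && min_height > 0 && min_prominence > 0)) {
    stop(imu_error("config_invalid", "detector thresholds must be positive"))
  }
  if (!(seglen_analysis %in% c(512L, 1024L) && seglen_classify %in% c(512L, 1024L))) {
    stop(imu_error("config_invalid", "segment lengths must be 512 or 1024"))
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the head-stabilization pipeline end to end
#'
#' Executes sync, calibration, prefiltering, gravity estimation, alignment,
#' step detection, cycling exclusion, bout grouping, per-step spectra and RMS,
#' the predominant-frequency gate, the four stability measures, and the
#' frequency-binned summaries, in that order. Every detected step is kept in
#' the step table with a `flags` column recording why it was excluded
#' (`cycling`, `singleton`, `out_of_gate`) or `retained`. The run log records
#' counts at every stage.
#'
#' @param config [pipeline_config()]
#' @param head,trunk [imu_recording()]s; read from `config` paths when omitted
#' @return list of class `headstab_run`: `steps` (per-step table), `bouts`,
#'   `summaries` (per-measure [binned_boxstats()]), `effects` (per-measure
#'   [kruskal_eta_squared()] results), `sync`, `calibration`, `log`, `config`
#' @export
run_pipeline <- function(config, head = NULL, trunk = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(head)) {
    if (is.null(config$head_path)) stop(imu_error("config_invalid", "no head recording"))
    head <- read_recording(config$head_path, "head")
  }
  if (is.null(trunk)) {
    if (is.null(config$trunk_path)) stop(imu_error("config_invalid", "no trunk recording"))
    trunk <- read_recording(config$trunk_path, "trunk")
  }
  fs <- trunk$sample_rate
  log <- list(n_samples = length(trunk$t))

  # --- synchronize ---------------------------------------------------------
  kh <- detect_knocks(head, config$knock_threshold, config$knock_refractory)
  kt <- detect_knocks(trunk, config$knock_threshold, config$knock_refractory)
  sync <- fit_sync(kh, kt)
  log$knocks_head <- length(kh); log$knocks_trunk <- length(kt)

  # --- calibrate -----------------------------------------------------------
  sw_h <- sync_head_time(sync, config$static_window)
  nw_h <- sync_head_time(sync, config$nod_window)
  cal_head <- fit_calibration(slice_recording(head, sw_h[1], sw_h[2]),
                              slice_recording(head, nw_h[1], nw_h[2]))
  cal_trunk <- fit_calibration(slice_recording(trunk, config$static_window[1],
                                               config$static_window[2]))
  head_c <- apply_calibration(head, cal_head)
  trunk_c <- apply_calibration(trunk, cal_trunk)

  # --- orientation and alignment ------------------------------------------
  head_f <- prefilter_imu(head_c, config$f_lp)
  trunk_f <- prefilter_imu(trunk_c, config$f_lp)
  est_head <- gravity_filter(head_f$accel, head_f$gyro, config$alpha, dt = 1 / fs)
  est_trunk <- gravity_filter(trunk_f$accel, trunk_f$gyro, config$alpha, dt = 1 / fs)
  al_head <- to_aligned(head_c$accel, est_head, gyro_body = head_f$gyro)
  al_trunk <- to_aligned(trunk_c$accel, est_trunk, gyro_body = trunk_f$gyro)

  # head channels resampled onto the trunk clock; cubic splines keep the
  # amplitude of high harmonics that linear interpolation would shave off
  th <- pmin(pmax(sync_head_time(sync, trunk$t), head$t[1]), head$t[length(head$t)])
  interp <- function(m) apply(m, 2L, function(col)
    stats::splinefun(head$t, col, method = "fmm")(th))
  head_inertial <- interp(al_head$inertial)
  head_pitch <- stats::splinefun(head$t, al_head$gyro_body[, 2L], method = "fmm")(th)
  trunk_inertial <- al_trunk$inertial
  trunk_pitch <- al_trunk$gyro_body[, 2L]

  # --- step detection ------------------------------------------------------
  v <- trunk_inertial[, "V"]
  peaks <- detect_step_peaks(v, fs, config$min_height, config$min_prominence,
                             config$min_distance)
  log$n_detected <- length(peaks)
  if (!length(peaks)) stop(imu_error("pipeline_no_steps", "no step peaks detected"))

  # --- per-step features (pass 1: frequencies and RMS) ---------------------
  ns <- length(peaks)
  axes <- c(AP = 1L, ML = 2L, V = 3L)
  sa <- config$seglen_analysis; sc <- config$seglen_classify
  feat <- data.frame(peak_index = peaks, peak_time = trunk$t[peaks])
  cls_f <- matrix(NA_real_, ns, 2L)
  f_tr <- rms_tr <- f_hd <- rms_hd <- matrix(NA_real_, ns, 3L)
  tr_sig <- lapply(1:3, function(a) trunk_inertial[, a])
  hd_sig <- lapply(1:3, function(a) head_inertial[, a])
  for (i in seq_len(ns)) {
    cls_f[i, 1L] <- predominant_frequency(step_spectrum(v, peaks[i], sc, fs))
    cls_f[i, 2L] <- predominant_frequency(
      step_spectrum(tr_sig[[2L]], peaks[i], sc, fs))
    for (a in 1:3) {
      sp_t <- step_spectrum(tr_sig[[a]], peaks[i], sa, fs)
      sp_h <- step_spectrum(hd_sig[[a]], peaks[i], sa, fs)
      f_tr[i, a] <- predominant_frequency(sp_t)
      f_hd[i, a] <- predominant_frequency(sp_h)
      rms_tr[i, a] <- segment_rms(tr_sig[[a]], peaks[i], sa)
      rms_hd[i, a] <- segment_rms(hd_sig[[a]], peaks[i], sa)
    }
  }
  feat$cls_f_V <- cls_f[, 1L]; feat$cls_f_ML <- cls_f[, 2L]
  feat[paste0("f_", names(axes))] <- f_tr
  feat[paste0("f_head_", names(axes))] <- f_hd
  feat[paste0("rms_", names(axes))] <- rms_tr
  feat[paste0("rms_head_", names(axes))] <- rms_hd

  # --- exclusions ----------------------------------------------------------
  flags <- rep("retained", ns)
  cyc <- classify_cycling(feat$rms_V, feat$cls_f_V, feat$cls_f_ML,
                          config$cycling_rms_threshold,
                          config$cycling_freq_mismatch)
  flags[cyc] <- "cycling"
  log$n_cycling <- sum(cyc)

  gb <- group_bouts(feat$peak_time[!cyc], config$max_gap,
                    pred_freq_v = feat$f_V[!cyc])
  feat$bout_id <- NA_integer_
  feat$bout_id[!cyc] <- gb$bout_id
  singleton <- !cyc & is.na(feat$bout_id)
  flags[singleton] <- "singleton"
  log$n_singleton <- sum(singleton)
  log$n_in_bouts <- sum(!cyc & !singleton)

  gated_out <- flags == "retained" & !frequency_gate(feat$f_head_V,
                                                     config$gate[1], config$gate[2])
  flags[gated_out] <- "out_of_gate"
  feat$flags <- flags
  log$n_out_of_gate <- sum(gated_out)
  log$n_retained <- sum(flags == "retained")
  log$retained_fraction <- log$n_retained / max(log$n_in_bouts, 1L)

  # --- stability measures (pass 2, retained steps only) --------------------
  meas_cols <- c("ac_AP", "ac_ML", "ac_V",
                 paste0("hr_head_", names(axes)), paste0("hr_trunk_", names(axes)),
                 "coh_hp_hv", "coh_hp_tp", "phase_hv_hp", "phase_hv_tp")
  meas <- matrix(NA_real_, ns, length(meas_cols),
                 dimnames = list(NULL, meas_cols))
  if (config$compute_measures && log$n_retained > 0L) {
    ret <- which(flags == "retained")
    hv <- hd_sig[[3L]]
    for (i in ret) {
      pk <- peaks[i]
      for (a in 1:3) {
        rh <- segment_rms(hd_sig[[a]], pk, sa, window = blackman_window)
        rt <- segment_rms(tr_sig[[a]], pk, sa, window = blackman_window)
        meas[i, a] <- attenuation_coefficient(rh, rt)
        meas[i, 6L + a] <- harmonic_ratio(
          step_spectrum(tr_sig[[a]], pk, sa, fs), f_tr[i, a],
          names(axes)[a], config$n_harmonics, config$hr_cap)
        meas[i, 3L + a] <- harmonic_ratio(
          step_spectrum(hd_sig[[a]], pk, sa, fs), f_hd[i, a],
          names(axes)[a], config$n_harmonics, config$hr_cap)
      }
      fd <- f_hd[i, 3L]
      meas[i, "coh_hp_hv"] <- coherence_at_fdom(head_pitch, hv, pk, fd, fs)
      meas[i, "coh_hp_tp"] <- coherence_at_fdom(head_pitch, trunk_pitch, pk, fd, fs)
      meas[i, "phase_hv_hp"] <- phase_difference(hv, head_pitch, pk, fs = fs,
                                                 seglen = sa)
      meas[i, "phase_hv_tp"] <- phase_difference(hv, trunk_pitch, pk, fs = fs,
                                                 seglen = sa)
    }
  }
  feat[meas_cols] <- meas

  # --- summaries -----------------------------------------------------------
  summaries <- NULL; effects <- NULL
  if (config$compute_measures && log$n_retained > 1L) {
    sm <- summarize_steps(feat, fs / sa, config$gate)
    summaries <- sm$boxstats
    effects <- sm$effects
  }

  run <- structure(list(steps = feat, bouts = gb$bouts, summaries = summaries,
                        effects = effects, sync = sync,
                        calibration = list(head = cal_head, trunk = cal_trunk),
                        log = log, config = config),
                   class = "headstab_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

#' @export
print.headstab_run <- function(x, ...) {
  l <- x$log
  cat(sprintf(paste0("<headstab_run> %d steps detected | %d cycling | %d singleton",
                     " | %d out of gate | %d retained (%.1f%% of bout steps)\n"),
              l$n_detected, l$n_cycling, l$n_singleton, l$n_out_of_gate,
              l$n_retained, 100 * l$retained_fraction))
  invisible(x)
}

#' Frequency-binned summaries and effect sizes for a step table
#'
#' @param steps step table from [run_pipeline()] (retained steps are used)
#' @param bin_width spectral-grid spacing, Hz
#' @param band analysis band, Hz
#' @return list with `boxstats` (named list of [binned_boxstats()] tables)
#'   and `effects` (data.frame of [kruskal_eta_squared()] results per measure)
#' @export
summarize_steps <- function(steps, bin_width = 100 / 512, band = c(1, 2.6)) {
  ret <- steps[steps$flags == "retained", ]
  measures <- c("rms_V", "rms_head_V", "ac_AP", "ac_ML", "ac_V",
                "hr_head_AP", "hr_head_ML", "hr_head_V",
                "hr_trunk_AP", "hr_trunk_ML", "hr_trunk_V",
                "coh_hp_hv", "coh_hp_tp", "phase_hv_hp", "phase_hv_tp")
  measures <- intersect(measures, names(ret))
  keys <- ret$f_head_V
  boxstats <- lapply(stats::setNames(measures, measures), function(m)
    binned_boxstats(ret[[m]], keys, bin_width, band))
  effects <- do.call(rbind, lapply(measures, function(m) {
    ok <- !is.na(ret[[m]]) & !is.na(keys)
    grp <- split(ret[[m]][ok], round(keys[ok] / bin_width))
    grp <- grp[lengths(grp) > 0]
    if (length(grp) < 2L || length(unique(unlist(grp))) < 2L) {
      return(data.frame(measure = m, eta_squared = NA_real_, label = NA_character_,
                        p_value = NA_real_, H = NA_real_, k = length(grp),
                        n = sum(ok)))
    }
    es <- kruskal_eta_squared(grp)
    data.frame(measure = m, eta_squared = es$eta_squared, label = es$label,
               p_value = es$p_value, H = es$H, k = es$k, n = es$n)
  }))
  list(boxstats = boxstats, effects = effects)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(run$steps, file.path(out_dir, "steps.csv"))
  data.table::fwrite(run$bouts, file.path(out_dir, "bouts.csv"))
  if (!is.null(run$summaries)) {
    for (m in names(run$summaries)) {
      data.table::fwrite(run$summaries[[m]],
                         file.path(out_dir, paste0("summary_", m, ".csv")))
    }
    data.table::fwrite(run$effects, file.path(out_dir, "effects.csv"))
  }
  lg <- run$log
  writeLines(c(sprintf("offset=%.6f drift=%.3g", run$sync$offset, run$sync$drift),
               paste0(names(lg), "=", vapply(lg, format, character(1)))),
             file.path(out_dir, "log.txt"))
  invisible(out_dir)
}

#' Simulate a session and write it to disk
#'
#' Wraps [generate_session()]: writes the head and trunk recordings as
#' delimited text plus the ground-truth sidecar.
#'
#' @param params [gait_params()]
#' @param duration seconds
#' @param out_dir output directory (created if needed)
#' @return named character vector of the three file paths (invisibly the
#'   `truth` object is attached as an attribute)
#' @export
simulate_session <- function(params, duration, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ses <- generate_session(params, duration)
  paths <- c(head = file.path(out_dir, "head.csv"),
             trunk = file.path(out_dir, "trunk.csv"),
             truth = file.path(out_dir, "truth.csv"))
  write_recording(ses$head, paths[["head"]])
  write_recording(ses$trunk, paths[["trunk"]])
  write_ground_truth(ses$truth, paths[["truth"]])
  attr(paths, "truth") <- ses$truth
  paths
}
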