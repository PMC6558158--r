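#' Detect candidate step peaks in vertical trunk acceleration
#'
#' Local maxima of the aligned vertical inertial acceleration satisfying a
#' minimum height, a minimum prominence (vertical distance to the highest of
#' the two lowest contour points before the next higher sample on each side),
#' and a minimum peak-to-peak distance. When two admissible peaks fall closer
#' than `min_distance`, the taller is kept; ties break toward the earlier
#' sample. The default 0.2 s distance corresponds to a maximum detectable
#' step frequency of 5 Hz.
#'
#' @param v numeric vertical acceleration, g (aligned frame)
#' @param fs sampling rate, Hz
#' @param min_height minimum peak height, g
#' @param min_prominence minimum prominence, g
#' @param min_distance minimum separation between kept peaks, s
#' Filters are applied in the order height, distance, prominence: a taller
#' local maximum suppresses its neighbors within `min_distance` even if it is
#' itself later discarded for lacking prominence.
#'
#' @return integer vector of peak sample indices (1-based), increasing
#' @export
detect_step_peaks <- function(v, fs = 100, min_height = 0.2,
                              min_prominence = 0.4, min_distance = 0.2) {
  n <- length(v)
  if (n < 3L) stop(imu_error("segmentation_short", "signal too short"))
  cand <- local_maxima(v)
  cand <- cand[v[cand] >= min_height]
  if (!length(cand)) return(integer(0))
  cand <- enforce_min_distance(cand, v[cand], round(min_distance * fs))
  prom <- peak_prominence(v, cand)
  cand[prom >= min_prominence]
}

# indices of strict local maxima; plateaus contribute their left edge
local_maxima <- function(x) {
  n <- length(x)
  d <- diff(x)
  rising <- which(d > 0)
  if (!length(rising)) return(integer(0))
  out <- integer(0)
  i <- 1L
  # a peak starts where d > 0 and the next nonzero slope is negative
  nz <- which(d != 0)
  sgn <- sign(d[nz])
  turn <- which(sgn[-length(sgn)] > 0 & sgn[-1L] < 0)
  out <- nz[turn] + 1L
  out
}

# scipy-style prominence: lowest contour line on each side up to the nearest
# higher sample (or the signal edge); prominence = height - max(side minima)
peak_prominence <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(i) {
    h <- x[i]
    l <- i - 1L
    lmin <- h
    while (l >= 1L && x[l] <= h) {
      if (x[l] < lmin) lmin <- x[l]
      l <- l - 1L
    }
    r <- i + 1L
    rmin <- h
    while (r <= n && x[r] <= h) {
      if (x[r] < rmin) rmin <- x[r]
      r <- r + 1L
    }
    h - max(lmin, rmin)
  }, numeric(1))
}

# greedy distance pruning: tallest first, ties toward the earlier sample;
# neighbors are located by binary search on the sorted positions
enforce_min_distance <- function(idx, height, min_samples) {
  if (min_samples <= 0L || length(idx) <= 1L) return(sort(idx))
  ord <- order(-height, idx)
  keep <- logical(length(idx))
  blocked <- logical(length(idx))
  pos <- idx
  for (j in ord) {
    if (blocked[j]) next
    keep[j] <- TRUE
    lo <- findInterval(pos[j] - min_samples, pos) + 1L
    hi <- findInterval(pos[j] + min_samples - 1L, pos)
    blocked[lo:hi] <- TRUE
  }
  sort(idx[keep])
}

#' Flag cycling-like steps
#'
#' Pedaling produces periodic vertical spikes that pass the step peak
#' detector, but with much lower vertical RMS than walking and with vertical
#' and medial/lateral predominant frequencies that do not match. A step is
#' flagged as cycling when `rms_v < rms_threshold` OR
#' `|freq_v - freq_ml| > freq_mismatch_threshold`. Flagged steps are removed
#' before bout grouping.
#'
#' @param rms_v vertical RMS per step, g
#' @param freq_v,freq_ml per-step predominant frequencies (trunk, from the
#'   1024-sample classification spectra), Hz
#' @param rms_threshold vertical RMS threshold, g
#' @param freq_mismatch_threshold allowed V-vs-ML frequency difference, Hz
#' @return logical vector, `TRUE` = cycling
#' @export
classify_cycling <- function(rms_v, freq_v, freq_ml, rms_threshold = 0.1,
                             freq_mismatch_threshold = 0.5) {
  rms_v < rms_threshold | abs(freq_v - freq_ml) > freq_mismatch_threshold
}

#' Group detected steps into walking bouts
#'
#' Maximal runs of steps whose consecutive peak-to-peak gaps are smaller than
#' `max_gap`; runs of a single step (no neighbor within `max_gap` on either
#' side) are discarded. If per-step vertical predominant frequencies are
#' supplied, the per-bout mean and SD are reported.
#'
#' @param peak_times step peak times, seconds, sorted increasing
#' @param max_gap maximum inter-step gap within a bout, s
#' @param pred_freq_v optional per-step vertical predominant frequency, Hz
#' @return list with `bout_id` (integer per step, `NA` = singleton excluded)
#'   and `bouts`, a data.frame with `bout`, `n_steps`, `t_first`, `t_last`,
#'   and (if frequencies were given) `mean_pred_freq_v`, `sd_pred_freq_v`
#' @export
group_bouts <- function(peak_times, max_gap = 1.0, pred_freq_v = NULL) {
  n <- length(peak_times)
  if (n == 0L) {
    return(list(bout_id = integer(0),
                bouts = data.frame(bout = integer(0), n_steps = integer(0),
                                   t_first = numeric(0), t_last = numeric(0))))
  }
  stopifnot(!is.unsorted(peak_times))
  new_run <- c(TRUE, diff(peak_times) >= max_gap)
  run <- cumsum(new_run)
  sizes <- tabulate(run)
  bout_id <- ifelse(sizes[run] >= 2L, run, NA_integer_)
  keep <- unique(run[sizes[run] >= 2L])
  bout_id <- match(bout_id, keep)
  bouts <- data.frame(
    bout = seq_along(keep),
    n_steps = sizes[keep],
    t_first = vapply(keep, function(r) min(peak_times[run == r]), numeric(1)),
    t_last = vapply(keep, function(r) max(peak_times[run == r]), numeric(1)))
  if (!is.null(pred_freq_v) && nrow(bouts)) {
    bouts$mean_pred_freq_v <- vapply(
      seq_along(keep), function(j) mean(pred_freq_v[!is.na(bout_id) & bout_id == j]),
      numeric(1))
    bouts$sd_pred_freq_v <- vapply(
      seq_along(keep), function(j) stats::sd(pred_freq_v[!is.na(bout_id) & bout_id == j]),
      numeric(1))
  }
  list(bout_id = bout_id, bouts = bouts)
}

#' Predominant-frequency gate
#'
#' Retains steps whose head vertical predominant frequency lies inside the
#' analysis band. The default band of 1 to 2.6 Hz corresponds to the walking
#' speeds for which the predominant frequency is an established proxy.
#'
#' @param head_pred_freq_v per-step head vertical predominant frequency, Hz
#' @param low,high band edges, Hz (inclusive)
#' @return logical vector, `TRUE` = retained
#' @export
frequency_gate <- function(head_pred_freq_v, low = 1.0, high = 2.6) {
  stopifnot(high > low)
  !is.na(head_pred_freq_v) & head_pred_freq_v >= low & head_pred_freq_v <= high
}
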