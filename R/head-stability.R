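#' Attenuation coefficient
#'
#' `AC = 1 - A_H / A_T`, from the RMS acceleration of head (`A_H`) and trunk
#' (`A_T`) over the same step segment and axis. Positive values indicate an
#' attenuation of head accelerations relative to the trunk; negative values
#' indicate amplification. Undefined (returned as `NA`) when the trunk RMS is
#' zero; such steps are excluded from AC summaries.
#'
#' @param rms_head,rms_trunk per-step RMS accelerations, g (vectorized)
#' @return numeric vector of attenuation coefficients (unitless, <= 1)
#' @export
attenuation_coefficient <- function(rms_head, rms_trunk) {
  out <- 1 - rms_head / rms_trunk
  out[!(rms_trunk > 0)] <- NA_real_
  out
}

#' Harmonic ratio of a step spectrum
#'
#' Ratio of total even-harmonic to total odd-harmonic spectral power of the
#' step cycle. The stride (two steps) is the fundamental period, so with
#' per-step predominant frequency `f_dom` the even harmonics of the stride
#' fall at `k * f_dom` and the odd harmonics at `(2k - 1) * f_dom / 2`,
#' `k = 1..n_harmonics`. In the AP and V directions accelerations are
#' biphasic within a stride and `HR = even / odd`; in the ML direction motion
#' is monophasic within a stride and the ratio is inverted (`odd / even`).
#' Each harmonic's power is read from the single nearest grid bin; harmonics
#' at or above the Nyquist frequency are truncated. A zero denominator
#' returns the configurable cap.
#'
#' @param spectrum [step_spectrum()]
#' @param f_dom predominant frequency of the segment in this direction, Hz
#' @param axis `"AP"`, `"ML"`, or `"V"`
#' @param n_harmonics harmonics per parity (default 10)
#' @param cap value returned when the denominator power is zero
#' @return harmonic ratio, unitless
#' @export
harmonic_ratio <- function(spectrum, f_dom, axis = c("V", "AP", "ML"),
                           n_harmonics = 10L, cap = 100) {
  axis <- match.arg(axis)
  if (is.na(f_dom) || f_dom <= 0) return(NA_real_)
  even_f <- (1:n_harmonics) * f_dom
  odd_f <- (2 * (1:n_harmonics) - 1) * f_dom / 2
  e <- sum_bins(spectrum, even_f)
  o <- sum_bins(spectrum, odd_f)
  num <- if (axis == "ML") o else e
  den <- if (axis == "ML") e else o
  if (den <= 0) return(cap)
  min(num / den, cap)
}

# sum spectrum power over the grid bins nearest the requested frequencies,
# dropping frequencies at or above Nyquist
sum_bins <- function(spectrum, freqs) {
  df <- spectrum$fs / spectrum$segment_length
  nyq <- spectrum$fs / 2
  freqs <- freqs[freqs < nyq]
  if (!length(freqs)) return(0)
  idx <- round(freqs / df) + 1L
  idx <- pmin(pmax(idx, 1L), length(spectrum$power))
  sum(spectrum$power[idx])
}

#' Welch magnitude-squared coherence at the predominant frequency
#'
#' A single step segment has an ill-defined coherence, so an extended
#' 1024-sample window centered on the step is divided into exactly five
#' Blackman-windowed sub-segments of 512 samples whose starts advance by 128
#' samples. `K^2 = |S_xy|^2 / (S_xx * S_yy)` with the cross- and auto-spectra
#' averaged over the five sub-segments, evaluated at the grid bin nearest
#' `f_dom`. Values are clamped into `[0, 1]` against floating-point overshoot.
#'
#' @param x,y numeric signals on a common time base
#' @param center center sample of the step
#' @param f_dom evaluation frequency, Hz
#' @param fs sampling rate, Hz
#' @return coherence in `[0, 1]`, or `NA` if either signal has no power at
#'   the evaluation bin
#' @export
coherence_at_fdom <- function(x, y, center, f_dom, fs = 100) {
  if (is.na(f_dom) || f_dom <= 0) return(NA_real_)
  seglen <- 512L
  segx <- centered_segment(x, center, 1024L)
  segy <- centered_segment(y, center, 1024L)
  w <- blackman_window(seglen)
  starts <- 0:4 * 128L
  bin <- round(f_dom * seglen / fs) + 1L
  bin <- min(max(bin, 1L), seglen / 2 + 1L)
  sxx <- syy <- 0
  sxy <- complex(real = 0, imaginary = 0)
  for (s in starts) {
    xs <- stats::fft(segx[(s + 1):(s + seglen)] * w)[bin]
    ys <- stats::fft(segy[(s + 1):(s + seglen)] * w)[bin]
    sxx <- sxx + Mod(xs)^2
    syy <- syy + Mod(ys)^2
    sxy <- sxy + xs * Conj(ys)
  }
  if (sxx <= 0 || syy <= 0) return(NA_real_)
  min(1, max(0, Mod(sxy / 5)^2 / ((sxx / 5) * (syy / 5))))
}

#' Phase difference between two quasi-periodic signals
#'
#' The lag of the cross-correlation maximum between `x` and `y` over
#' 512-sample step-centered segments, searched within one period of `x` and
#' converted to phase by dividing by the period (estimated from the first
#' non-zero-lag autocorrelation peak of `x`) times 2 pi. Both peak locations
#' are refined by three-point parabolic interpolation, which removes the
#' sample-grid quantization of the lag. Segments are mean-removed and
#' Blackman-weighted to suppress edge effects. The `correction` accounts for
#' comparing acceleration against angular velocity instead of displacement
#' against angle: integrating a sinusoid shifts its phase by -pi/2, twice for
#' acceleration-to-displacement and once for velocity-to-angle, so the net
#' correction is `2 * (-pi/2) - (-pi/2) = -pi/2`. The result is wrapped to
#' `(-pi, pi]`.
#'
#' A positive raw difference means `y` leads `x`; a delay of `y` by a quarter
#' period of `x` gives a raw difference of `-pi/2`.
#'
#' @param x,y numeric signals on a common time base (`x` quasi-periodic)
#' @param center center sample of the step
#' @param correction additive phase correction, radians (default `-pi/2`)
#' @param fs sampling rate, Hz
#' @param seglen segment length, samples
#' @return corrected phase difference in `(-pi, pi]`, radians, or `NA` when
#'   `x` has no autocorrelation peak (aperiodic)
#' @export
phase_difference <- function(x, y, center, correction = -pi / 2, fs = 100,
                             seglen = 512L) {
  segx <- centered_segment(x, center, seglen)
  segy <- centered_segment(y, center, seglen)
  w <- blackman_window(seglen)
  segx <- (segx - mean(segx)) * w
  segy <- (segy - mean(segy)) * w
  period <- autocorr_period(segx)
  if (is.na(period)) return(NA_real_)
  r <- cross_correlation(segx, segy)
  lags <- -(seglen - 1L):(seglen - 1L)
  within <- abs(lags) <= ceiling(period)
  ri <- r[within]; li <- lags[within]
  j <- which.max(ri)
  lag <- parabolic_peak(ri, j) + li[1] - 1
  phase <- -2 * pi * lag / period + correction
  wrap_phase(phase)
}

# linear cross-correlation r(tau) = sum_t x(t) y(t + tau), tau = -(n-1)..(n-1)
cross_correlation <- function(x, y) {
  n <- length(x)
  m <- stats::nextn(2L * n, 2)
  X <- stats::fft(c(x, rep(0, m - n)))
  Y <- stats::fft(c(y, rep(0, m - n)))
  r <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / m
  # circular layout: tau = 0..n-1 at r[1..n], tau = -(n-1)..-1 at r[m-n+2..m]
  c(r[(m - n + 2):m], r[1:n])
}

# period (samples, fractional) from the first non-zero-lag autocorrelation
# peak; NA when no local maximum exists
autocorr_period <- function(x) {
  n <- length(x)
  r <- cross_correlation(x, x)[n:(2L * n - 1L)] # lags 0..n-1
  if (all(abs(r) < .Machine$double.eps)) return(NA_real_)
  # first local maximum at lag >= 2 samples; small noise ripples are skipped
  # by requiring the peak to reach a quarter of the zero-lag value
  cand <- local_maxima(r)
  cand <- cand[cand >= 3L & r[cand] > 0.25 * r[1L]] # index 1 is lag 0
  if (!length(cand)) return(NA_real_)
  j <- cand[1L]
  parabolic_peak(r, j) - 1
}

# three-point parabolic refinement of a peak at integer index j; returns the
# fractional index of the vertex
parabolic_peak <- function(r, j) {
  if (j <= 1L || j >= length(r)) return(as.numeric(j))
  y1 <- r[j - 1L]; y2 <- r[j]; y3 <- r[j + 1L]
  den <- y1 - 2 * y2 + y3
  if (abs(den) < .Machine$double.eps) return(as.numeric(j))
  j + 0.5 * (y1 - y3) / den
}

wrap_phase <- function(p) {
  w <- p - 2 * pi * floor((p + pi) / (2 * pi))
  ifelse(w <= -pi, w + 2 * pi, w)
}
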