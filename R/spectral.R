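#' Short-time power spectrum of a step-centered segment
#'
#' Windowed periodogram of a `seglen`-sample segment centered on a detected
#' step peak. Segments that overrun the recording edge are zero-padded
#' symmetrically. Power is one-sided and normalized so that the sum over the
#' frequency grid equals the mean square of the windowed time-domain segment
#' (a discrete Parseval identity); only ratios and the argmax are used
#' downstream, so the normalization convention is immaterial there.
#'
#' @param x numeric signal
#' @param center center sample (1-based index)
#' @param seglen segment length in samples: 512 or 1024 (powers of two)
#' @param fs sampling rate, Hz
#' @param window window function (defaults to the Blackman window)
#' @return object of class `step_spectrum`: `freqs` (Hz), `power`,
#'   `segment_length`, `window`, `center_index`, `fs`
#' @export
step_spectrum <- function(x, center, seglen = 512L, fs = 100,
                          window = blackman_window) {
  if (!(seglen %in% c(512L, 1024L))) {
    stop(imu_error("spectral_seglen", "seglen must be 512 or 1024"))
  }
  if (seglen > length(x)) {
    stop(imu_error("spectral_too_short", "segment longer than signal"))
  }
  seg <- centered_segment(x, center, seglen)
  w <- window(seglen)
  xw <- seg * w
  X <- stats::fft(xw)
  half <- seglen / 2L
  p_full <- Mod(X)^2 / seglen^2
  power <- p_full[1:(half + 1L)]
  power[2:half] <- power[2:half] + rev(p_full)[1:(half - 1L)]
  freqs <- (0:half) * fs / seglen
  structure(list(freqs = freqs, power = power, segment_length = seglen,
                 window = "blackman", center_index = center, fs = fs),
            class = "step_spectrum")
}

# seglen-sample window centered on `center`, symmetric zero-padding at edges
centered_segment <- function(x, center, seglen) {
  lo <- center - seglen %/% 2L
  hi <- lo + seglen - 1L
  if (lo >= 1L && hi <= length(x)) return(x[lo:hi])
  idx <- lo:hi
  seg <- numeric(seglen)
  ok <- idx >= 1L & idx <= length(x)
  seg[ok] <- x[idx[ok]]
  seg
}

# Blackman windows reused across the per-step loops
.window_cache <- new.env(parent = emptyenv())
blackman_window <- function(n) {
  key <- as.character(n)
  if (is.null(.window_cache[[key]])) {
    .window_cache[[key]] <- signal::blackman(n)
  }
  .window_cache[[key]]
}

#' @export
print.step_spectrum <- function(x, ...) {
  cat(sprintf("<step_spectrum> seglen=%d  df=%.4g Hz  peak=%.3g Hz\n",
              x$segment_length, x$fs / x$segment_length,
              x$freqs[-1][which.max(x$power[-1])]))
  invisible(x)
}

#' Predominant frequency of a step spectrum
#'
#' Frequency of maximum spectral power within `band`, excluding the DC bin
#' (gravity residuals would otherwise dominate). Ties break toward the lower
#' frequency.
#'
#' @param spectrum [step_spectrum()]
#' @param band two-element band `c(low, high)` in Hz, default the full grid
#' @return frequency in Hz, or `NA_real_` if the spectrum has no power in the
#'   band
#' @export
predominant_frequency <- function(spectrum, band = NULL) {
  f <- spectrum$freqs
  pw <- spectrum$power
  keep <- f > 0
  if (!is.null(band)) {
    stopifnot(length(band) == 2L, band[2] > band[1])
    keep <- keep & f >= band[1] & f <= band[2]
  }
  if (!any(keep)) stop(imu_error("spectral_empty_band", "no bins in band"))
  f <- f[keep]; pw <- pw[keep]
  if (all(pw == 0)) return(NA_real_)
  f[which.max(pw)]
}

#' RMS of a step-centered segment
#'
#' Root mean square of the centered segment, per the magnitude summaries; by
#' default the raw (unwindowed) samples are used. The attenuation-coefficient
#' computation weights the segment with a Blackman window first to de-emphasize
#' non-locomotor samples at the segment edges (`window = blackman_window`).
#'
#' @inheritParams step_spectrum
#' @param window `NULL` for unwindowed RMS, or a window function
#' @return RMS in the units of `x`
#' @export
segment_rms <- function(x, center, seglen = 512L, window = NULL) {
  if (seglen > length(x)) {
    stop(imu_error("spectral_too_short", "segment longer than signal"))
  }
  seg <- centered_segment(x, center, seglen)
  if (!is.null(window)) seg <- seg * window(seglen)
  sqrt(mean(seg^2))
}
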