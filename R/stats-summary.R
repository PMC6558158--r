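#' Kruskal-Wallis effect size (eta squared)
#'
#' Effect size of a grouping factor on a measure,
#' `eta^2 = (H - k + 1) / (n - k)`, where `H` is the tie-corrected
#' Kruskal-Wallis statistic, `k` the number of groups and `n` the total sample
#' size. Effect sizes are labeled small for `eta^2 < 0.04`, intermediate for
#' `0.04 < eta^2 < 0.11` and large for `eta^2 > 0.11`. For near-identical
#' groups `eta^2` can be slightly negative; it is reported as computed and
#' labeled small.
#'
#' @param groups list of numeric vectors, one per group (k >= 2, each
#'   non-empty, total n > k)
#' @return object of class `effect_size`: `eta_squared`, `label`, `p_value`,
#'   `H`, `k`, `n`
#' @export
kruskal_eta_squared <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(!vapply(groups, length, 0L))) {
    stop(imu_error("stats_empty_group", "every group must be non-empty"))
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  k <- length(groups)
  n <- length(x)
  if (n <= k) stop(imu_error("stats_too_few", "need n > k samples"))
  if (length(unique(x)) == 1L) {
    stop(imu_error("stats_all_tied",
                   "all values identical; H is undefined under full ties"))
  }
  kt <- stats::kruskal.test(x, g)
  H <- unname(kt$statistic)
  eta <- (H - k + 1) / (n - k)
  label <- if (eta < 0.04) "small" else if (eta > 0.11) "large" else "intermediate"
  structure(list(eta_squared = eta, label = label,
                 p_value = unname(kt$p.value), H = H, k = k, n = n),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> eta^2=%.4f (%s)  H=%.3f  k=%d  n=%d  p=%.3g\n",
              x$eta_squared, x$label, x$H, x$k, x$n, x$p_value))
  invisible(x)
}

#' Frequency-binned boxplot statistics
#'
#' Summarizes a per-step measure as a function of predominant frequency, the
#' way the study-style figures are drawn. Bins are the spectral grid
#' frequencies of the 512-sample analysis spectra (spacing `fs / 512` Hz)
#' spanning the analysis band; every value is assigned to the nearest grid
#' bin. Quartiles use linear interpolation (R type 7); whiskers extend to the
#' most extreme samples within 1.5 interquartile ranges of the nearer
#' quartile; samples beyond the whiskers are counted as outliers but not
#' listed. Empty bins are reported with `n = 0` and undefined quartiles.
#'
#' @param values numeric measure per step
#' @param bin_keys predominant frequency per step, Hz (same length)
#' @param bin_width frequency-grid spacing, Hz (default `100/512`)
#' @param band analysis band, Hz
#' @return data.frame of class `freq_binned_summary` with columns
#'   `bin_center`, `n`, `q1`, `median`, `q3`, `whisker_low`, `whisker_high`,
#'   `n_outliers`
#' @export
binned_boxstats <- function(values, bin_keys, bin_width = 100 / 512,
                            band = c(1, 2.6)) {
  stopifnot(length(values) == length(bin_keys))
  keep <- !is.na(values) & !is.na(bin_keys)
  values <- values[keep]; bin_keys <- bin_keys[keep]
  kmin <- ceiling(band[1] / bin_width - 1e-9)
  kmax <- floor(band[2] / bin_width + 1e-9)
  centers <- (kmin:kmax) * bin_width
  assign_k <- round(bin_keys / bin_width)
  out <- lapply(kmin:kmax, function(k) {
    v <- values[assign_k == k]
    if (!length(v)) {
      return(data.frame(bin_center = k * bin_width, n = 0L, q1 = NA_real_,
                        median = NA_real_, q3 = NA_real_,
                        whisker_low = NA_real_, whisker_high = NA_real_,
                        n_outliers = 0L))
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- v[v >= lo_fence & v <= hi_fence]
    data.frame(bin_center = k * bin_width, n = length(v), q1 = q[1],
               median = q[2], q3 = q[3],
               whisker_low = min(inside), whisker_high = max(inside),
               n_outliers = sum(v < lo_fence | v > hi_fence))
  })
  res <- do.call(rbind, out)
  class(res) <- c("freq_binned_summary", "data.frame")
  res
}
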