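test_that("attenuation coefficient follows its definition", {
  expect_equal(attenuation_coefficient(0.3, 0.3), 0)
  expect_equal(attenuation_coefficient(0.15, 0.3), 0.5)
  expect_equal(attenuation_coefficient(0.6, 0.3), -1)
  expect_true(is.na(attenuation_coefficient(0.1, 0)))
  # vectorized and always <= 1 for non-negative RMS
  set.seed(40)
  h <- runif(100); tr <- runif(100)
  ac <- attenuation_coefficient(h, tr)
  expect_true(all(ac <= 1))
})

test_that("harmonic ratio sums the even and odd harmonic ladders", {
  fs <- 100
  df <- fs / 512
  f_dom <- 20 * df # on-grid step frequency, 3.906 Hz
  t <- (0:2047) / fs
  n <- 1:10
  even <- rowSums(sapply(n, function(k) cos(2 * pi * k * f_dom * t)))
  odd <- rowSums(sapply(n, function(k)
    cos(2 * pi * (2 * k - 1) * f_dom / 2 * t)))
  # power only at even harmonics: odd power zero, AP/V ratio hits the cap
  sp_even <- step_spectrum(even, 1024L, 512L, fs)
  expect_equal(harmonic_ratio(sp_even, f_dom, "V"), 100)
  expect_equal(harmonic_ratio(sp_even, f_dom, "ML"), 0, tolerance = 1e-4)
  # equal power at every harmonic: HR = 1 in both conventions
  sp_eq <- step_spectrum(even + odd, 1024L, 512L, fs)
  expect_equal(harmonic_ratio(sp_eq, f_dom, "V"), 1, tolerance = 1e-3)
  expect_equal(harmonic_ratio(sp_eq, f_dom, "ML"), 1, tolerance = 1e-3)
  # even:odd power 4:1 (odd amplitudes halved)
  sp41 <- step_spectrum(even + 0.5 * odd, 1024L, 512L, fs)
  expect_equal(harmonic_ratio(sp41, f_dom, "V"), 4, tolerance = 5e-3)
  expect_equal(harmonic_ratio(sp41, f_dom, "AP"), 4, tolerance = 5e-3)
  expect_equal(harmonic_ratio(sp41, f_dom, "ML"), 0.25, tolerance = 5e-3)
  # matches a direct nearest-bin summation oracle
  idx_even <- round((1:10) * f_dom / df) + 1L
  idx_odd <- round((2 * (1:10) - 1) * f_dom / 2 / df) + 1L
  oracle <- sum(sp41$power[idx_even]) / sum(sp41$power[idx_odd])
  expect_equal(harmonic_ratio(sp41, f_dom, "V"), oracle, tolerance = 1e-12)
})

test_that("harmonics above Nyquist are truncated", {
  fs <- 100
  f_dom <- 12 # 10th harmonic at 120 Hz would alias
  t <- (0:2047) / fs
  x <- cos(2 * pi * 12 * t) + cos(2 * pi * 24 * t) + cos(2 * pi * 6 * t)
  sp <- step_spectrum(x, 1024L, 512L, fs)
  hr <- harmonic_ratio(sp, f_dom, "V")
  expect_true(is.finite(hr))
  expect_gt(hr, 1) # two even harmonics in band vs one odd
})

test_that("coherence is exact for linearly dependent signals", {
  set.seed(41)
  x <- rnorm(2048)
  k <- coherence_at_fdom(x, 3 * x, 1024L, f_dom = 2)
  expect_equal(k, 1, tolerance = 1e-6)
  kneg <- coherence_at_fdom(x, -0.5 * x, 1024L, f_dom = 3.9)
  expect_equal(kneg, 1, tolerance = 1e-6)
  expect_true(is.na(coherence_at_fdom(rep(0, 2048), x, 1024L, 2)))
})

test_that("coherence of independent noise shows the five-segment Welch bias", {
  # brute-force Monte-Carlo oracle: same estimator structure written out
  # naively against which the implementation's mean bias is compared
  set.seed(42)
  welch5 <- function(x, y, bin) {
    w <- signal::blackman(512)
    sxx <- syy <- 0; sxy <- 0 + 0i
    for (s in 0:4 * 128) {
      X <- fft((x[(s + 1):(s + 512)] - 0) * w)[bin]
      Y <- fft((y[(s + 1):(s + 512)] - 0) * w)[bin]
      sxx <- sxx + Mod(X)^2; syy <- syy + Mod(Y)^2; sxy <- sxy + X * Conj(Y)
    }
    Mod(sxy)^2 / (sxx * syy)
  }
  n_rep <- 120
  imp <- ora <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    x <- rnorm(1024); y <- rnorm(1024)
    # center 513 makes the extended window cover the signal exactly
    imp[r] <- coherence_at_fdom(x, y, 513L, f_dom = 10)
    ora[r] <- welch5(x, y, round(10 * 512 / 100) + 1)
  }
  expect_equal(imp, ora, tolerance = 1e-12)
  # the bias of a 5-segment (heavily overlapped) estimate is large and positive
  expect_gt(mean(imp), 0.1)
  expect_lt(mean(imp), 0.6)
})

test_that("coherence stays inside [0, 1]", {
  set.seed(43)
  for (r in 1:50) {
    x <- rnorm(1024); y <- 0.5 * x + rnorm(1024)
    k <- coherence_at_fdom(x, y, 512L, f_dom = runif(1, 0.5, 40))
    expect_gte(k, 0); expect_lte(k, 1)
  }
})

test_that("phase differences recover constructed lags with the -pi/2 correction", {
  fs <- 100
  t <- (0:1023) / fs
  f0 <- 2
  x <- cos(2 * pi * f0 * t)
  # y = x: raw 0, corrected -pi/2
  expect_equal(phase_difference(x, x, 512L), -pi / 2, tolerance = 1e-3)
  # y delayed by a quarter period: raw -pi/2, corrected -pi (wrapped to +pi)
  y <- cos(2 * pi * f0 * (t - 0.125))
  ph <- phase_difference(x, y, 512L)
  expect_equal(abs(ph), pi, tolerance = 1e-2)
  # random true offsets recovered within the one-sample phase quantum
  set.seed(44)
  for (r in 1:20) {
    beta <- runif(1, -2.5, 2.5)
    y2 <- cos(2 * pi * f0 * t + beta)
    raw <- phase_difference(x, y2, 512L, correction = 0)
    expect_lt(abs(raw - beta), 2 * pi * f0 / fs)
  }
  # aperiodic x: undefined
  expect_true(is.na(phase_difference(rep(0, 1024), x, 512L)))
})

test_that("stability measures are invariant to positive rescaling", {
  ses <- noiseless_session()
  truth <- ses$truth
  long_bout <- truth$bouts$bout[which.max(truth$bouts$n_steps)]
  mid <- which(truth$step_bouts == long_bout)
  ctr <- round(truth$step_times[mid[ceiling(length(mid) / 2)]] * 100) + 1L
  hv <- ses$head$accel[, 3] - mean(ses$head$accel[, 3])
  hp <- ses$head$gyro[, 2]
  sp <- step_spectrum(hv, ctr, 512L, 100)
  fd <- predominant_frequency(sp)
  base <- list(
    ac = attenuation_coefficient(segment_rms(hv, ctr, 512L),
                                 segment_rms(2 * hv, ctr, 512L)),
    hr = harmonic_ratio(sp, fd, "V"),
    coh = coherence_at_fdom(hp, hv, ctr, fd),
    ph = phase_difference(hv, hp, ctr))
  s <- 7.3
  sp_s <- step_spectrum(s * hv, ctr, 512L, 100)
  expect_equal(harmonic_ratio(sp_s, fd, "V"), base$hr, tolerance = 1e-9)
  expect_equal(coherence_at_fdom(s * hp, s * hv, ctr, fd), base$coh,
               tolerance = 1e-9)
  expect_equal(phase_difference(s * hv, s * hp, ctr), base$ph,
               tolerance = 1e-9)
  expect_equal(attenuation_coefficient(s * segment_rms(hv, ctr, 512L),
                                       s * segment_rms(2 * hv, ctr, 512L)),
               base$ac, tolerance = 1e-12)
})
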