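test_that("self-coherence is identically one and scaling-invariant", {
  set.seed(11)
  fs <- 100
  x <- rnorm(30 * fs)
  cs <- msc(x, x, fs)
  expect_true(all(abs(cs$coherence - 1) < 1e-12))
  y <- rnorm(30 * fs)
  c1 <- msc(x, y, fs)
  c2 <- msc(5 * x, 0.2 * y, fs)
  expect_equal(c1$coherence, c2$coherence, tolerance = 1e-10)
  expect_equal(msc(x, y, fs)$coherence, msc(y, x, fs)$coherence)
  expect_true(all(c1$coherence >= 0 & c1$coherence <= 1))
  expect_error(msc(x[1:(5 * fs)], y[1:(5 * fs)], fs), "2 segments")
  expect_error(msc(x, y[1:10], fs), "equal length")
})

test_that("independent-noise coherence shows the known 1/M estimator bias", {
  set.seed(12)
  fs <- 100
  for (M in c(10, 40)) {
    x <- rnorm(M * 2 * fs)
    y <- rnorm(M * 2 * fs)
    cs <- msc(x, y, fs, segment_s = 2, overlap = 0)
    expect_equal(attr(cs, "n_segments"), M)
    bias <- mean(cs$coherence[-c(1, nrow(cs))])
    expect_gt(bias, 0.5 / M)
    expect_lt(bias, 2 / M)
  }
})

test_that("imaginary coherence suppresses zero-lag mixtures but not delays", {
  set.seed(13)
  fs <- 200
  n <- 120 * fs
  x <- rnorm(n)
  # instantaneous mixture: IC ~ 0 within estimator noise 3/sqrt(M)
  ic0 <- imag_coherence(x, 0.7 * x + 0.1 * rnorm(n), fs, segment_s = 2,
                        overlap = 0)
  M <- attr(ic0, "n_segments")
  expect_lt(max(ic0$coherence[-c(1, nrow(ic0))]), 3 / sqrt(M))
  # pure delay d: IC ~ |sin(2 pi f d)| sqrt(C)
  d <- 25
  y <- c(rep(0, d), x[1:(n - d)])
  ic <- imag_coherence(x, y, fs, segment_s = 2, overlap = 0)
  ms <- msc(x, y, fs, segment_s = 2, overlap = 0)
  sel <- ic$freq > 2 & ic$freq < 90
  pred <- abs(sin(2 * pi * ic$freq[sel] * d / fs)) *
    sqrt(ms$coherence[sel])
  expect_lt(mean(abs(ic$coherence[sel] - pred)), 0.1)
})

test_that("cross-correlation peak recovers shifts exactly with sign conventions", {
  set.seed(14)
  fs <- 1000
  x <- rnorm(2 * fs)
  pk <- xcorr_peak(x, x, fs)
  expect_equal(pk$correlation, 1)
  expect_equal(pk$lag, 0)
  # y delayed by +35 ms -> positive lag, exact integer-sample recovery
  d <- 35
  y <- c(rep(0, d), x[1:(length(x) - d)])
  pk <- xcorr_peak(x, y, fs)
  expect_equal(pk$lag, d / fs)
  expect_lt(abs(pk$correlation - 1), 1e-12)
  # anti-correlated pair: |peak| at a negative extremum, sign reported
  pk2 <- xcorr_peak(x, -y, fs)
  expect_equal(pk2$lag, d / fs)
  expect_lt(pk2$correlation, -0.99)
  # positive-peak variant ignores the negative extremum
  pk3 <- xcorr_peak(x, -y, fs, peak = "positive")
  expect_gt(pk3$correlation, -0.1)
  expect_error(xcorr_peak(rep(1, 100), rnorm(100), fs, 0.01),
               "zero-variance")
  expect_error(xcorr_peak(x, y, fs, max_lag = 10), "shorter")
})

test_that("lag recovery over seeds is unbiased for the injected delay", {
  meds <- vapply(c(21, 22, 23), function(s) {
    sess <- simulate_session(seed = s, n_wake = 0, n_nrem = 0, n_rem = 12)
    truth <- sess$bursts[sess$bursts$state == "REM", ]
    ld <- lag_distribution(sess, truth, "DR")
    ld$median_lag
  }, numeric(1))
  expect_lt(abs(mean(meds) - 0.035), 0.001)
})

test_that("lag distribution object is internally consistent", {
  sess <- cached_session()
  truth <- sess$bursts[sess$bursts$state == "REM", ]
  ld <- lag_distribution(sess, truth, "DR")
  expect_equal(ld$n_events, length(ld$lags))
  expect_true(all(abs(ld$correlations) <= 1))
  # CDF is non-decreasing from 0 to 1 and crosses 0.5 at the median
  grid <- seq(-0.1, 0.1, by = 1e-3)
  cdf_vals <- ld$cdf(grid)
  expect_true(all(diff(cdf_vals) >= 0))
  expect_equal(range(cdf_vals), c(0, 1))
  expect_gte(ld$cdf(ld$median_lag), 0.5)
  expect_error(lag_distribution(sess, truth[1, , drop = FALSE]), "2 events")
})

test_that("burst-triggered coherence exceeds the sliding-window level in DR", {
  sess <- cached_session()
  rem <- epochize(sess, "REM")
  ev <- detect_bursts(channel_trace(sess, "CA1_DR"), sess$fs, epochs = rem)
  band <- c(10, 14)
  band_mean <- function(cs) {
    mean(cs$coherence[cs$freq >= band[1] & cs$freq <= band[2]])
  }
  bt_ca1 <- burst_triggered_coherence(sess, ev, "CA1", "DR")
  sliding <- state_msc(sess, "REM", "DR")
  expect_gt(band_mean(bt_ca1), band_mean(sliding))
  # the choice of the triggering area does not change the result materially
  ev_pfc <- detect_bursts(channel_trace(sess, "PFC_DR"), sess$fs,
                          epochs = rem)
  bt_pfc <- burst_triggered_coherence(sess, ev_pfc, "PFC", "DR")
  expect_equal(band_mean(bt_ca1), band_mean(bt_pfc), tolerance = 0.15)
  # random windows fall back towards the sliding-window level
  set.seed(9)
  fake <- data.frame(
    onset = sort(runif(nrow(ev), min(rem$start) + 1,
                       max(rem$start) + 14)),
    duration = 1)
  bt_fake <- burst_triggered_coherence(sess, fake, "CA1", "DR")
  expect_lt(band_mean(bt_fake), band_mean(bt_ca1) - 0.2)
  expect_error(burst_triggered_coherence(sess, ev[1, , drop = FALSE],
                                         "CA1", "DR"), "2 events")
})

test_that("a common distal source inflates RR coherence that IC unmasks", {
  sess <- cached_session()
  ms <- state_msc(sess, "REM", "RR")
  ic <- state_msc(sess, "REM", "RR", variant = "imaginary")
  k <- which.min(abs(ms$freq - 7))
  # conducted theta: strong RR magnitude-squared coherence at 7 Hz
  expect_gt(ms$coherence[k], 0.3)
  # but near-zero imaginary coherence (zero-lag coupling)
  expect_lt(ic$coherence[k], ms$coherence[k] / 3)
})

test_that("coherence degrades with noise along the expected curve", {
  cv <- coherence_vs_noise(c(0, 5, 10, 20), n_segments = 500, seed = 5)
  expect_equal(cv$coherence[cv$noise_sd == 0], 1, tolerance = 1e-9)
  expect_true(all(diff(cv$coherence) < 0))
  # flat-noise theory: C = 1 / (1 + sd^2/100) for 400-sample segments
  expect_lt(abs(cv$coherence[cv$noise_sd == 10] - 0.5), 0.05)
  expect_lt(abs(cv$coherence[cv$noise_sd == 20] - 0.2), 0.05)
})

test_that("sech fitting recovers a known scale and basic identities hold", {
  x <- c(1, 2, 5, 10, 15, 20, 30)
  exact <- data.frame(noise_sd = x, coherence = 1 / cosh(0.13 * x))
  f <- fit_sech(exact)
  expect_equal(f$a, 0.13, tolerance = 1e-6)
  expect_lt(f$residual_rms, 1e-7)
  # sech(a * 0) = 1 for any a
  f0 <- fit_sech(data.frame(noise_sd = c(0, 1, 2),
                            coherence = 1 / cosh(0.4 * c(0, 1, 2))))
  expect_equal(f0$fitted[1], 1)
  expect_warning(
    fit_sech(data.frame(noise_sd = 1:3, coherence = c(0.2, 0.8, 0.1))),
    "monotone")
  expect_error(fit_sech(data.frame(noise_sd = 1:2, coherence = c(1, 0.5))),
               "3 points")
})
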