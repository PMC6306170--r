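test_that("epochize returns the state's slices and warns when absent", {
  sess <- simulate_session(seed = 8, n_wake = 2, n_nrem = 0, n_rem = 10)
  ep <- epochize(sess, "REM")
  expect_equal(nrow(ep), 10)
  expect_true(all(ep$duration == 15))
  expect_warning(empty <- epochize(sess, "NREM"), "no 'NREM' epochs")
  expect_equal(nrow(empty), 0)
  # 15 s epochs resolve finer than 0.1 Hz
  expect_equal(freq_resolution(15), 1 / 15)
  expect_lt(freq_resolution(15), 0.1)
})

test_that("Welch PSD localises a pure sine and satisfies Parseval", {
  fs <- 200
  tt <- seq(0, 60, by = 1 / fs)[-1]
  x <- sin(2 * pi * 7 * tt)
  ps <- welch_psd(x, fs)
  expect_equal(ps$freq[which.max(ps$power)], 7, tolerance = 1e-9)
  expect_true(all(ps$power >= 0))
  # frequency step is the reciprocal of the segment duration
  expect_equal(diff(ps$freq[1:2]), 1 / attr(ps, "segment_s"))
  # white noise: integrated density recovers the variance within 5%
  set.seed(2)
  w <- rnorm(120 * fs, sd = 3)
  pw <- welch_psd(w, fs)
  expect_equal(band_power(pw, c(0, fs / 2)), var(w), tolerance = 0.05)
})

test_that("Welch averaging is invariant to epoch ordering and replication", {
  sess <- cached_session()
  ps1 <- state_spectrum(sess, "REM", "DR", "CA1")
  ps2 <- state_spectrum(sess, "REM", "DR", "CA1")
  expect_equal(ps1$power, ps2$power)
  # averaging N identical epochs equals the single-epoch estimate
  fs <- 100
  x <- sin(2 * pi * 5 * seq(0, 15, by = 1 / fs))[-1]
  one <- welch_psd(x, fs)
  rep3 <- welch_psd(c(x, x, x), fs)
  # compare at matched overlap positions: use non-overlapping segments
  one0 <- welch_psd(x, fs, overlap = 0)
  rep0 <- welch_psd(c(x, x, x), fs, overlap = 0)
  expect_equal(one0$power, rep0$power, tolerance = 1e-10)
})

test_that("state spectra show the state-dependent oscillators", {
  sess <- cached_session()
  rem_dr <- state_spectrum(sess, "REM", "DR", "CA1")
  nrem_dr <- state_spectrum(sess, "NREM", "DR", "CA1")
  peak_at <- function(ps, lo, hi) {
    sel <- ps$freq >= lo & ps$freq <= hi
    ps$freq[sel][which.max(ps$power[sel])]
  }
  # REM theta peak near 7 Hz
  expect_equal(peak_at(rem_dr, 4, 10), 7, tolerance = 0.15)
  # NREM slow oscillation dominates below 4 Hz
  expect_gt(band_power(nrem_dr, c(0.5, 2)), band_power(nrem_dr, c(6, 10)))
  expect_error(state_spectrum(sess, "REM", segment_s = 20), "shorter")
})

test_that("spectrogram tracks stationary and chirped frequencies", {
  fs <- 200
  tt <- seq(0, 20, by = 1 / fs)[-1]
  # stationary sine: constant ridge at 5 Hz, map normalised to max 1
  tf <- spectrogram(sin(2 * pi * 5 * tt), fs)
  expect_equal(max(tf$power), 1)
  ridge <- tf$freq[apply(tf$power, 2, which.max)]
  expect_true(all(abs(ridge - 5) <= 1))
  # linear chirp 2 -> 22 Hz over 20 s: ridge tracks f(t) = 2 + t
  ch <- sin(2 * pi * (2 * tt + 0.5 * tt^2))
  tfc <- spectrogram(ch, fs)
  ridge_c <- tfc$freq[apply(tfc$power, 2, which.max)]
  expected <- 2 + tfc$time
  inner <- tfc$time > 1 & tfc$time < 19
  expect_lt(max(abs(ridge_c[inner] - expected[inner])), 1.5)
  expect_error(spectrogram(tt[1:50], fs, window_s = 1), "longer than trace")
})

test_that("a REM burst appears as transient 10-14 Hz energy in both areas' maps", {
  sess <- cached_session()
  truth <- sess$bursts[sess$bursts$state == "REM", ]
  ev <- truth[1, ]
  fs <- sess$fs
  idx <- (round((ev$onset - 5) * fs) + 1):(round((ev$onset + 5) * fs))
  for (area in c("CA1", "PFC")) {
    x <- channel_trace(sess, paste0(area, "_DR"))[idx]
    tf <- spectrogram(x, fs)
    bsel <- tf$freq >= 10 & tf$freq <= 14
    bandpow <- colSums(tf$power[bsel, , drop = FALSE])
    # the within-window peak of sigma-band power falls at the burst time
    t_peak <- tf$time[which.max(bandpow)]
    expect_equal(t_peak, 5 + ev$duration / 2, tolerance = 0.5)
  }
})
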