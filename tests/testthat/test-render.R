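test_that("rendering is linear in source amplitude and zero without sources", {
  h <- build_hypnogram(0, 0, 2, seed = 1)
  ens <- build_sources(h, seed = 1)
  # no sources -> all electrode channels zero (EMG is a separate generator)
  ens0 <- ens
  ens0$sources <- list()
  s0 <- render(ens0)
  expect_true(all(s0$traces[, c("CA1_e1", "CA1_e2", "PFC_e1", "PFC_e2",
                                "REF")] == 0))
  # doubling one source's amplitude doubles its contribution exactly
  s1 <- render(ens)
  ens2 <- ens
  ens2$sources[[1]]$amplitude <- 2 * ens2$sources[[1]]$amplitude
  s2 <- render(ens2)
  only <- ens
  only$sources <- ens$sources[1]
  sc <- render(only)
  expect_equal(s2$traces[, "CA1_e1"],
               s1$traces[, "CA1_e1"] + sc$traces[, "CA1_e1"])
})

test_that("a single distal source is attenuated in DR per the distal law", {
  h <- build_hypnogram(0, 0, 2, seed = 2)
  ens <- build_sources(h, seed = 2)
  only <- ens
  only$sources <- Filter(function(s) s$role == "distal_common", ens$sources)
  sess <- render(only)
  rr <- channel_trace(sess, "CA1_RR")
  dr <- channel_trace(sess, "CA1_DR")
  # expected amplitude ratio from the geometry, via the coordinate oracle
  src <- only$sources[[1]]
  ep <- electrode_positions(sess$montage$pairs$CA1)
  g1 <- 1 / sqrt(sum((ep["e1", ] - src$position)^2))
  g2 <- 1 / sqrt(sum((ep["e2", ] - src$position)^2))
  gref <- 1 / sqrt(sum((sess$montage$reference - src$position)^2))
  expected <- (g1 - g2) / (g1 - gref)
  expect_equal(sd(dr) / sd(rr), abs(expected), tolerance = 1e-6)
  # and the distal closed form 2*eps*cos(alpha)/r^2 approximates it
  geom <- source_pair_geometry(src, sess$montage$pairs$CA1)
  distal_over_rr <- 2 * sess$montage$pairs$CA1$half_separation *
    geom$cos_alpha / geom$r^2 / (g1 - gref)
  expect_equal(sd(dr) / sd(rr), abs(distal_over_rr), tolerance = 0.01)
  # DR power suppression of the common source matches the squared
  # amplitude ratio within 10%
  expect_equal(mean(dr^2) / mean(rr^2), expected^2, tolerance = 0.1)
})

test_that("rendering is deterministic and rejects singular geometry", {
  h <- build_hypnogram(1, 1, 1, seed = 3)
  ens <- build_sources(h, seed = 3)
  expect_identical(render(ens)$traces, render(ens)$traces)
  bad <- ens
  bad$sources[[1]]$position <-
    electrode_positions(ens$montage$pairs$CA1)["e1", ]
  expect_error(render(bad), "coincides")
})

test_that("referential power exceeds differential power ~10-fold in REM", {
  sess <- cached_session()
  idx <- state_indices(sess, "REM")
  rr <- channel_trace(sess, "CA1_RR")[idx]
  dr <- channel_trace(sess, "CA1_DR")[idx]
  ratio <- mean(rr^2) / mean(dr^2)
  expect_gt(ratio, 5)
  expect_lt(ratio, 20)
  # same check through the Welch spectra
  ps_rr <- state_spectrum(sess, "REM", "RR", "CA1")
  ps_dr <- state_spectrum(sess, "REM", "DR", "CA1")
  spec_ratio <- band_power(ps_rr, c(0.5, 100)) / band_power(ps_dr, c(0.5, 100))
  expect_gt(spec_ratio, 5)
  expect_lt(spec_ratio, 20)
})

test_that("EMG power tracks the vigilance state", {
  sess <- cached_session()
  emg <- channel_trace(sess, "EMG")
  lv <- vapply(c("Wake", "NREM", "REM"), function(st) {
    sqrt(mean(emg[state_indices(sess, st)]^2))
  }, numeric(1))
  expect_gt(lv[["Wake"]], 2 * lv[["NREM"]])
  expect_gt(lv[["NREM"]], 2 * lv[["REM"]])
})
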