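test_that("build_hypnogram realises the requested epoch counts exactly", {
  h <- build_hypnogram(n_wake = 5, n_nrem = 12, n_rem = 7, epoch_length = 15,
                       seed = 3)
  tab <- table(h$state)
  expect_equal(unname(tab[["Wake"]]), 5)
  expect_equal(unname(tab[["NREM"]]), 12)
  expect_equal(unname(tab[["REM"]]), 7)
  expect_true(all(h$duration == 15))
  # contiguity
  expect_equal(h$start, cumsum(c(0, head(h$duration, -1))))
})

test_that("default counts give the scored sleep time of the study design", {
  h <- build_hypnogram(seed = 1)
  sleep_s <- sum(h$duration[h$state %in% c("NREM", "REM")])
  expect_equal(sleep_s, (195 + 110) * 15)  # 4575 s
  expect_equal(hypnogram_duration(h), (55 + 195 + 110) * 15)
})

test_that("hypnogram generation is seed-reproducible and degenerate cases error", {
  expect_identical(build_hypnogram(3, 4, 5, seed = 9),
                   build_hypnogram(3, 4, 5, seed = 9))
  expect_false(identical(build_hypnogram(3, 4, 5, seed = 9)$state,
                         build_hypnogram(3, 4, 5, seed = 10)$state))
  h1 <- build_hypnogram(1, 0, 0, seed = 1)
  expect_equal(nrow(h1), 1)
  expect_equal(h1$state, "Wake")
  expect_error(build_hypnogram(0, 0, 0), "zero")
  expect_error(hypnogram(c(0, 10), c(5, 5), c("Wake", "REM")), "contiguous")
  expect_error(hypnogram(0, -1, "Wake"), "positive")
})

test_that("source scheduling is state-conditioned and Poisson-calibrated", {
  # REM-only hypnogram with zero burst rate: only theta, backgrounds and the
  # common source carry energy
  h <- build_hypnogram(0, 0, 4, seed = 2)
  p0 <- source_params(burst_rate = 0, spindle_rate = 0)
  ens <- build_sources(h, p0, seed = 2)
  expect_equal(nrow(ens$bursts), 0)
  active <- vapply(ens$sources, function(s) sd(s$waveform) > 0, logical(1))
  roles <- vapply(ens$sources, function(s) s$role, "")
  expect_true(all(roles[active] %in%
                    c("local_CA1", "background", "distal_common")))
  # Poisson mean: lambda = 6/min over 10 min of REM -> ~60 events
  h10 <- build_hypnogram(0, 0, 40, seed = 3)  # 600 s REM
  counts <- vapply(1:12, function(s) {
    nrow(build_sources(h10, source_params(), seed = s)$bursts)
  }, numeric(1))
  # edge margins trim the usable window slightly; mean must sit near 60
  expect_gt(mean(counts), 45)
  expect_lt(mean(counts), 70)
})

test_that("burst schedule carries the configured delay and validates it", {
  h <- build_hypnogram(0, 0, 6, seed = 4)
  ens <- build_sources(h, seed = 4)
  rem <- ens$bursts[ens$bursts$state == "REM", ]
  expect_true(all(rem$delay == 0.035))
  expect_true(all(rem$areas == "both"))
  expect_true(all(rem$freq >= 10 & rem$freq <= 14))
  expect_error(source_params(burst_delay = 1.2, burst_duration = 1),
               "delay")
})

test_that("source building is deterministic given the seed", {
  h <- build_hypnogram(2, 3, 3, seed = 5)
  e1 <- build_sources(h, seed = 11)
  e2 <- build_sources(h, seed = 11)
  expect_identical(e1$bursts, e2$bursts)
  expect_identical(e1$sources[[1]]$waveform, e2$sources[[1]]$waveform)
})
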