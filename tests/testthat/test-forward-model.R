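test_that("current density follows the inverse-square law and conserves flux", {
  src <- current_source(c(0, 0, 0), 4 * pi)
  expect_equal(current_density(src, 1), 1)
  expect_equal(current_density(src, 2), 0.25)
  # total flux through a sphere of any radius equals the source current
  for (r in c(0.01, 0.5, 3, 100)) {
    expect_equal(4 * pi * r^2 * current_density(src, r), src$amplitude)
  }
  expect_error(current_density(src, 0), "positive")
  expect_error(current_density(src, -1), "positive")
})

test_that("point potential is I/(4 pi sigma r), linear in I and 1/sigma", {
  src <- current_source(c(0, 0, 0), 4 * pi)
  expect_equal(point_potential(src, c(1, 0, 0), medium(1)), 1)
  # 1/r law
  expect_equal(point_potential(src, c(2, 0, 0), medium(1)),
               point_potential(src, c(1, 0, 0), medium(1)) / 2)
  # linear in current, inverse in conductivity
  src2 <- current_source(c(0, 0, 0), 8 * pi)
  expect_equal(point_potential(src2, c(1, 0, 0), medium(1)),
               2 * point_potential(src, c(1, 0, 0), medium(1)))
  expect_equal(point_potential(src, c(1, 0, 0), medium(2)),
               point_potential(src, c(1, 0, 0), medium(1)) / 2)
  expect_error(point_potential(src, c(0, 0, 0), medium(1)), "singular")
})

test_that("superposition: summed potentials match the coordinate oracle", {
  set.seed(42)
  med <- medium(0.3)
  for (i in 1:10) {
    s1 <- current_source(rnorm(3), runif(1, 0.5, 2) * 1e-6)
    s2 <- current_source(rnorm(3), runif(1, 0.5, 2) * 1e-6)
    p <- rnorm(3) * 2
    expect_equal(
      point_potential(s1, p, med) + point_potential(s2, p, med),
      oracle_potential(s1$amplitude, 0.3, s1$position, p) +
        oracle_potential(s2$amplitude, 0.3, s2$position, p)
    )
  }
})

test_that("pair potentials match direct evaluation at the contact coordinates", {
  set.seed(1)
  med <- medium(0.3)
  for (i in 1:20) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    pr <- electrode_pair(rnorm(3) * 1e-3, ax, runif(1, 5e-5, 2e-4))
    src <- current_source(rnorm(3) * 5e-3, 1e-6)
    v <- pair_potentials(src, pr, med)
    ep <- electrode_positions(pr)
    expect_equal(unname(v["V1"]),
                 oracle_potential(1e-6, 0.3, src$position, ep["e1", ]))
    expect_equal(unname(v["V2"]),
                 oracle_potential(1e-6, 0.3, src$position, ep["e2", ]))
  }
})

test_that("pair potential geometry: broadside symmetry and on-axis ratio", {
  med <- medium(1)
  pr <- electrode_pair(c(0, 0, 0), c(1, 0, 0), 1)
  # alpha = pi/2: equidistant contacts
  v <- pair_potentials(current_source(c(0, 5, 0), 1), pr, med)
  expect_equal(unname(v["V1"]), unname(v["V2"]))
  # alpha = 0, r = 2 eps: distances eps and 3 eps, so V1/V2 = 3
  v <- pair_potentials(current_source(c(2, 0, 0), 1), pr, med)
  expect_equal(unname(v["V1"] / v["V2"]), 3)
})

test_that("pair difference regimes behave per their closed forms", {
  med <- medium(0.3)
  eps <- 1e-4
  pr <- electrode_pair(c(0, 0, 0), c(1, 0, 0), eps)
  # distal at alpha = pi/2 vanishes (broadside null)
  d <- pair_difference(current_source(c(0, 1e-2, 0), 1e-6), pr, med, "distal")
  expect_equal(d$value, 0)
  # local at alpha = pi/2 vanishes (cos 45 = sin 45)
  l <- pair_difference(current_source(c(0, eps, 0), 1e-6), pr, med, "local")
  expect_equal(l$value, 0, tolerance = 1e-12)
  # local regime singular on the axis
  expect_error(
    pair_difference(current_source(c(eps, 0, 0), 1e-6), pr, med, "local"),
    "singular")
  # exact vs distal on-axis at r = 100 eps: relative error = (eps/r)^2 = 1e-4
  src <- current_source(c(100 * eps, 0, 0), 1e-6)
  ex <- pair_difference(src, pr, med, "exact")$value
  di <- pair_difference(src, pr, med, "distal")$value
  # closed forms: exact = k*2eps/(r^2-eps^2), distal = k*2eps/r^2
  expect_equal(abs(ex - di) / abs(ex), 1e-4, tolerance = 1e-6)
})

test_that("local law equals the exact law at r = eps for any alpha", {
  med <- medium(0.3)
  eps <- 1e-4
  pr <- electrode_pair(c(0, 0, 0), c(1, 0, 0), eps)
  for (a in seq(0.1, pi - 0.1, length.out = 15)) {
    src <- current_source(eps * c(cos(a), sin(a), 0), 1e-6)
    expect_equal(pair_difference(src, pr, med, "local")$value,
                 pair_difference(src, pr, med, "exact")$value,
                 tolerance = 1e-10)
  }
})

test_that("distal approximation error decreases monotonically in r and is bounded", {
  med <- medium(0.3)
  eps <- 1e-4
  pr <- electrode_pair(c(0, 0, 0), c(1, 0, 0), eps)
  rel_err <- function(r_over_eps, alpha) {
    src <- current_source(r_over_eps * eps * c(cos(alpha), sin(alpha), 0),
                          1e-6)
    ex <- pair_difference(src, pr, med, "exact")$value
    di <- pair_difference(src, pr, med, "distal")$value
    abs(ex - di) / abs(ex)
  }
  # monotone decrease with distance on-axis, and <= 1e-3 beyond 100 eps
  errs <- vapply(c(10, 20, 50, 100, 200, 500), rel_err, numeric(1), alpha = 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(rel_err(100, 0), 1e-3)
  expect_lt(rel_err(300, 0), 1e-3)
  # uniform second-order bound over angle: coefficient |5 cos^2 a - 3| / 2
  # never exceeds 3/2, so 1.6 (eps/r)^2 bounds the error everywhere
  for (r in c(10, 30, 100)) {
    for (a in seq(0.05, pi / 2 - 0.05, length.out = 12)) {
      expect_lt(rel_err(r, a), 1.6 / r^2)
    }
  }
})

test_that("distal pair difference is maximal on-axis and antisymmetric about pi/2", {
  med <- medium(0.3)
  eps <- 1e-4
  pr <- electrode_pair(c(0, 0, 0), c(1, 0, 0), eps)
  val <- function(alpha) {
    pair_difference(current_source(5e-3 * c(cos(alpha), sin(alpha), 0), 1e-6),
                    pr, med, "distal")$value
  }
  alphas <- seq(0, pi / 2, length.out = 10)
  vals <- vapply(alphas, val, numeric(1))
  expect_true(all(diff(vals) < 0))        # decreasing from alpha = 0
  expect_equal(which.max(vals), 1L)       # maximum on-axis
  for (a in c(0.3, 0.7, 1.2)) {
    expect_equal(val(pi / 2 + a), -val(pi / 2 - a), tolerance = 1e-12)
  }
})

test_that("CMRR evaluates to the tabulated values and scales quadratically", {
  expect_equal(cmrr(10, 1), sqrt(2) / 4 * 100)
  expect_equal(round(cmrr(10, 1)), 35)
  expect_equal(signif(cmrr(100, 1), 2), 3500)
  # quadratic law, sigma-independence is structural (no sigma argument)
  for (r in c(0.3, 2, 17)) {
    expect_equal(cmrr(2 * r, 1) / cmrr(r, 1), 4)
  }
  expect_error(cmrr(-1, 1), "positive")
  expect_error(cmrr(1, 0), "positive")
})

test_that("SNR expressions reproduce the montage comparison identities", {
  expect_equal(snr_rr(6, 1), 6)
  expect_equal(snr_dr(6, 1), 36 * sqrt(2) / 4)
  expect_equal(floor(snr_dr(6, 1)), 12)
  expect_equal(round(snr_gain(6, 1)), 2)
  expect_equal(snr_global(6, 1, 3), 8)
  # unity gain exactly at r = 2 sqrt(2) eps
  expect_equal(snr_gain(2 * sqrt(2), 1), 1)
  # identities over random geometry
  set.seed(5)
  for (i in 1:20) {
    r <- runif(1, 0.1, 50)
    eps <- runif(1, 0.01, 1)
    expect_equal(snr_dr(r, eps), cmrr(r, eps))
    expect_equal(snr_gain(r, eps) * snr_rr(r, eps), snr_dr(r, eps))
  }
  expect_error(snr_global(6, 1, 0), "positive integer")
})

test_that("theory table collects the montage quantities consistently", {
  tb <- theory_table(c(6, 10))
  expect_equal(tb$cmrr, tb$snr_dr)
  expect_equal(tb$snr_global[tb$r_over_eps == 6], 8)
  expect_equal(round(tb$cmrr[tb$r_over_eps == 10]), 35)
})
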