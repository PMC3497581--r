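test_that("circular_mean handles the canonical symmetric cases", {
  for (th in c(0, 37, 213.4, 359)) {
    m <- circular_mean(th)
    expect_equal(m$mu_deg, th)
    expect_equal(m$r, 1)
  }
  m <- circular_mean(c(0, 90))
  expect_equal(m$mu_deg, 45)
  expect_equal(m$r, sqrt(2) / 2)
  m <- circular_mean(c(10, 350))
  expect_equal(m$mu_deg, 0)
  expect_equal(m$r, cos(10 * pi / 180))
  expect_error(circular_mean(numeric(0)), "empty")
  expect_error(circular_mean(c(1, NA)), "non-finite")
  # antipodal pair: r = 0, direction undefined
  m <- circular_mean(c(0, 180))
  expect_equal(m$r, 0, tolerance = 1e-12)
  expect_true(is.na(m$mu_deg))
})

test_that("dispersion and concentration reproduce printed table rows", {
  expect_equal(circular_dispersion(0.88)$circ_variance, 0.12)
  expect_equal(circular_dispersion(0.65)$circ_sd_deg, 53.18, tolerance = 1e-3)
  expect_equal(circular_dispersion(1), list(circ_variance = 0, circ_sd_deg = 0))
  expect_true(is.infinite(circular_dispersion(0)$circ_sd_deg))
  expect_error(circular_dispersion(1.2), "\\[0, 1\\]")

  expect_equal(vonmises_kappa(0, 44), 0)
  # printed Concentration values (2-dp rounding of r limits agreement)
  expect_gt(vonmises_kappa(0.68, 44), 1.88)
  expect_lt(vonmises_kappa(0.68, 44), 1.89)
  expect_gt(vonmises_kappa(0.74, 6), 1.27)
  expect_lt(vonmises_kappa(0.74, 6), 1.29)
  expect_true(is.na(vonmises_kappa(0.9, 1)))
  expect_true(is.infinite(vonmises_kappa(1, 10)))
})

test_that("vonmises_kappa is nondecreasing in r where the estimator is continuous", {
  # without the small-sample correction (n > 15) monotonicity holds globally
  for (n in c(16, 40, 500)) {
    k <- vapply(seq(0, 0.999, by = 0.001), vonmises_kappa, numeric(1), n = n)
    expect_true(all(diff(k) >= -1e-12), info = paste("n =", n))
  }
  # the n <= 15 bias correction has a genuine discontinuity at the
  # uncorrected kappa = 2 switch point; monotone on each side of it
  for (n in c(2, 6, 15)) {
    rs <- seq(0, 0.999, by = 0.001)
    k_raw <- vapply(rs, vonmises_kappa, numeric(1), n = 16)  # uncorrected shape
    k <- vapply(rs, vonmises_kappa, numeric(1), n = n)
    below <- k_raw < 2
    expect_true(all(diff(k[below]) >= -1e-12), info = paste("n =", n, "low"))
    expect_true(all(diff(k[!below]) >= -1e-12), info = paste("n =", n, "high"))
  }
})

test_that("Rayleigh second-order series reproduces printed p-values", {
  # (n, r) -> printed P, from the published per-genus summary tables
  cases <- list(c(1, 1.00, 0.512), c(12, 0.59, 0.012), c(17, 0.57, 0.003),
                c(41, 0.34, 0.008), c(14, 0.60, 0.005))
  for (cs in cases) {
    out <- rayleigh_test(r = cs[2], n = cs[1])
    expect_equal(out$Z, cs[1] * cs[2]^2)
    expect_equal(round(out$P, 3), cs[3])
  }
  expect_equal(round(rayleigh_test(r = 0.93, n = 4)$P, 2), 0.02)
  out <- rayleigh_test(r = 0, n = 100)
  expect_equal(out$Z, 0)
  expect_equal(out$P, 1)
})

test_that("Rao spacing statistic matches its closed forms", {
  expect_equal(rao_spacing_U(c(0, 90, 180, 270)), 0)
  # evenly spaced at any n and rotation
  expect_equal(rao_spacing_U(wrap_deg(17 + seq(0, 359, by = 360 / 12))), 0)
  # all-identical angles: maximal U = 360 - 360/n
  for (n in c(4, 7, 12)) {
    expect_equal(rao_spacing_U(rep(77, n)), 360 - 360 / n)
  }
  r <- rao_spacing_test(rep(200, 10))
  expect_equal(r$label, "< 0.01")
  r <- rao_spacing_test(c(0, 90, 180, 270))
  expect_equal(r$label, "P > 0.99")
  # below minimum n: undefined flag
  r <- rao_spacing_test(c(10, 20, 30))
  expect_true(is.na(r$U))
  expect_equal(r$label, "-")
})

test_that("Rao bracket covers the true p-value under the null", {
  # uniform n = 30 samples: the printed bracket should contain 0.5 most of
  # the time (the true P of a typical null draw is near the middle)
  set.seed(1001)
  cover <- replicate(1000, {
    out <- rao_spacing_test(runif(30, 0, 360))
    out$P_lower <= 0.5 && out$P_upper >= 0.5
  })
  expect_gte(mean(cover), 0.8)
})

test_that("Rao Monte Carlo mode gives a continuous, seeded p-value", {
  a <- c(3, 9, 15, 170, 181, 192, 200, 355)
  r1 <- rao_spacing_test(a, method = "montecarlo", reps = 500, seed = 4)
  r2 <- rao_spacing_test(a, method = "montecarlo", reps = 500, seed = 4)
  expect_equal(r1$P_mc, r2$P_mc)
  expect_gt(r1$P_mc, 0)
  expect_lt(r1$P_mc, 1)
  # MC p agrees with the bracket
  expect_gte(r1$P_mc, r1$P_lower - 0.05)
  expect_lte(r1$P_mc, r1$P_upper + 0.05)
})

test_that("rotation equivariance holds for the whole summary block", {
  set.seed(2)
  for (i in 1:20) {
    a <- runif(sample(4:40, 1), 0, 360)
    phi <- runif(1, -720, 720)
    s0 <- circ_summary(a)
    s1 <- circ_summary(wrap_deg(a + phi))
    expect_equal(ang_diff(s1$mu_deg, wrap_deg(s0$mu_deg + phi)), 0, tolerance = 1e-8)
    for (f in c("r", "kappa", "circ_variance", "circ_sd_deg",
                "rayleigh_Z", "rayleigh_P", "rao_U")) {
      expect_equal(s1[[f]], s0[[f]], tolerance = 1e-9)
    }
  }
})

test_that("summary block invariants hold exactly", {
  set.seed(3)
  for (i in 1:25) {
    a <- runif(sample(1:30, 1), 0, 360)
    s <- circ_summary(a)
    expect_identical(s$circ_variance, 1 - s$r)
    expect_identical(s$rayleigh_Z, s$n * s$r^2)
    expect_true(s$r >= 0 && s$r <= 1)
    if (s$n == 1) expect_true(is.na(s$kappa))
    if (s$n < 4) expect_true(is.na(s$rao_U))
  }
})

test_that("circular-linear correlation: exact, degenerate and null cases", {
  set.seed(4)
  th <- runif(50, 0, 360)
  out <- circ_linear_correlation(th, cos(th * pi / 180))
  expect_equal(out$circ_R2, 1, tolerance = 1e-9)
  expect_lt(out$circ_P, 1e-6)

  out <- circ_linear_correlation(th, rep(2.5, 50))
  expect_false(out$defined)
  expect_true(is.na(out$circ_R2))

  # independent covariate: R2 near zero, P not extreme
  x <- rnorm(500)
  th <- runif(500, 0, 360)
  out <- circ_linear_correlation(th, x, lengths = rgamma(500, 2))
  expect_lt(out$circ_R2, 0.05)
  expect_gt(out$circ_P, 1e-4)
  expect_error(circ_linear_correlation(th, x[1:10]), "paired")
  expect_error(circ_linear_correlation(th[1:3], x[1:3]), "n >= 4")
})

test_that("rvonmises samples concentrate around mu and reduce to uniform", {
  set.seed(5)
  a <- rvonmises(2000, 230, 8)
  m <- circular_mean(a)
  expect_lt(ang_diff(m$mu_deg, 230), 3)
  expect_gt(m$r, 0.8)
  u <- rvonmises(2000, 0, 0)
  expect_gt(rayleigh_test(circular_mean(u)$r, 2000)$P, 0.01)
  expect_true(all(u >= 0 & u < 360))
})
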