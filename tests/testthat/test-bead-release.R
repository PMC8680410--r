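test_that("release law evaluates the printed constants correctly", {
  cpo <- beadParams("CPO")
  hog <- beadParams("HOG")
  # zero oxygen, time zero: Hill gate is 1, rate is the peak G_n
  expect_equal(beadReleaseRate(0, 0, cpo), 2.2)
  # at the half-saturation oxygen the gate halves the peak
  expect_equal(beadReleaseRate(0.11, 0, cpo), 1.1)
  # exponential decay limit
  expect_lt(beadReleaseRate(0, 200, cpo), 1e-12)
  # CPO decays faster than HOG by exp(-(0.5 - 0.05) t)
  expect_equal(beadReleaseRate(0, 2, cpo) / beadReleaseRate(0, 2, hog),
               exp(-0.9), tolerance = 1e-12)
  expect_error(beadReleaseRate(-0.1, 0, cpo), ">= 0")
  expect_error(beadReleaseRate(0, -1, cpo), ">= 0")
})

test_that("release rate is monotone, bounded, and orders CPO below HOG", {
  cpo <- beadParams("CPO"); hog <- beadParams("HOG")
  tt <- seq(0, 14, by = 0.25)
  cc <- c(0, 0.02, 0.05, 0.11, 0.2, 0.5, 1)
  for (c0 in cc) {
    r <- beadReleaseRate(c0, tt, cpo)
    expect_true(all(diff(r) < 0))                        # decreasing in t
    expect_true(all(r <= cpo$G_n * exp(-cpo$tau * tt) + 1e-15))
  }
  for (t0 in c(0, 1, 5)) {
    r <- beadReleaseRate(cc, t0, hog)
    expect_true(all(diff(r) <= 0))                       # non-increasing in c
  }
  # sustained-release design: HOG beats CPO at any t > 0
  expect_true(all(beadReleaseRate(0.05, tt[-1], hog) >
                  beadReleaseRate(0.05, tt[-1], cpo)))
})

test_that("cumulative zero-oxygen release matches its quadrature oracle", {
  cpo <- beadParams("CPO"); hog <- beadParams("HOG")
  expect_identical(cumulativeReleaseZeroOxygen(0, cpo), 0)
  expect_equal(cumulativeReleaseZeroOxygen(Inf, cpo), 4.4)
  expect_equal(cumulativeReleaseZeroOxygen(Inf, hog), 44)
  # HOG total budget is tenfold the CPO budget
  expect_equal(cumulativeReleaseZeroOxygen(Inf, hog) /
               cumulativeReleaseZeroOxygen(Inf, cpo), 10)
  for (tend in c(0.5, 3, 14)) {
    for (par in list(cpo, hog)) {
      quad <- stats::integrate(function(t) beadReleaseRate(0, t, par),
                               0, tend, rel.tol = 1e-12)$value
      expect_equal(cumulativeReleaseZeroOxygen(tend, par), quad,
                   tolerance = 1e-8)
    }
  }
  expect_error(cumulativeReleaseZeroOxygen(
    1, list(G_n = 2.2, H_n = 0.11, hill_h = 6, tau = 0)), "nonzero")
})

test_that("bead placement hits the target count, stays in bounds, and is seeded", {
  b <- placeBeads(100, 100, 0.02, "HOG", seed = 11)
  expect_identical(nBeads(b), 200L)
  s <- beadSites(b)
  expect_true(all(s[, 1] >= 1 & s[, 1] <= 100 & s[, 2] >= 1 & s[, 2] <= 100))
  expect_false(anyDuplicated(s) > 0)

  expect_identical(nBeads(placeBeads(50, 50, 0, "CPO", seed = 1)), 0L)
  b2 <- placeBeads(100, 100, 0.02, "HOG", seed = 11)
  expect_identical(beadSites(b2), s)               # determinism
  b3 <- placeBeads(100, 100, 0.02, "HOG", seed = 12)
  expect_false(identical(beadSites(b3), s))
  expect_error(placeBeads(10, 10, 1.5, "CPO"), "fraction")

  # placement must not disturb the caller's RNG stream
  set.seed(99); before <- .Random.seed
  placeBeads(30, 30, 0.05, "CPO", seed = 3)
  expect_identical(.Random.seed, before)
})

test_that("release parameters are recovered exactly from noiseless curves", {
  for (tau_true in c(0.5, 0.05)) {
    cv <- makeReleaseCurve(seq(0, 12, by = 0.5), G_n = 2.2, tau = tau_true)
    fit <- fitReleaseParams(cv)
    expect_equal(fit$G_n, 2.2, tolerance = 1e-6)
    expect_equal(fit$tau, tau_true, tolerance = 1e-6)
    expect_lt(fit$residual_norm, 1e-8)
  }
})

test_that("release-parameter recovery is robust to measurement noise", {
  rel_err <- vapply(1:50, function(s) {
    cv <- makeReleaseCurve(seq(0, 14, by = 0.5), G_n = 2.2, tau = 0.05,
                           noise_sd = 0.05, seed = s)
    abs(fitReleaseParams(cv)$tau - 0.05) / 0.05
  }, numeric(1))
  expect_lt(stats::median(rel_err), 0.10)
})

test_that("degenerate and unidentifiable fits are rejected", {
  flat <- new("ReleaseCurve", times = 0:9, rates = rep(0, 10),
              oxygen = 0, noise_sd = 0)
  expect_error(fitReleaseParams(flat), "degenerate")
  short <- makeReleaseCurve(0:3, G_n = 2.2, tau = 0.5)
  expect_error(fitReleaseParams(short), "at least 5")
  cv <- makeReleaseCurve(seq(0, 12, 0.5), G_n = 2.2, tau = 0.5)
  expect_error(fitReleaseParams(cv, fixH = FALSE), "not identifiable")
})

test_that("the Hill half-saturation is estimable from oxygen-varying curves", {
  tt <- seq(0, 10, by = 0.25)
  oxy <- rep(c(0, 0.05, 0.1, 0.15), length.out = length(tt))
  cv <- makeReleaseCurve(tt, G_n = 2.2, tau = 0.2, oxygen = oxy)
  fit <- fitReleaseParams(cv, fixH = FALSE,
                          params = beadParams("CPO"))
  expect_equal(fit$H_n, 0.11, tolerance = 1e-4)
  expect_equal(fit$tau, 0.2, tolerance = 1e-5)
})
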