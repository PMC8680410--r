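test_that("field initialization matches the implant starting state", {
  fld <- initializeFields(small_cfg(), defaultParameters())
  expect_equal(oxygenToPercent(mean(oxygenField(fld))), 3.7)
  expect_equal(mean(matrixField(fld)), 0.1)
  expect_equal(mean(progenitorField(fld)), 0.1)
  expect_identical(mean(vegfField(fld)), 0)
  expect_identical(mean(fibroblastField(fld)), 0)
  expect_identical(simTime(fld), 0)
})

test_that("oxygen states classify against the 0.5% and 5% thresholds", {
  expect_identical(classifyOxygen(percentToNondim(0.3)), "anoxic")
  expect_identical(classifyOxygen(percentToNondim(3.7)), "hypoxic")
  expect_identical(classifyOxygen(percentToNondim(21)), "normoxic")
  # boundary semantics: anoxic strictly below 0.5%, hypoxic from 0.5%
  expect_identical(classifyOxygen(percentToNondim(c(0.4999, 0.5, 4.9999, 5))),
                   c("anoxic", "hypoxic", "hypoxic", "normoxic"))
  expect_error(classifyOxygen(-0.1), ">= 0")
})

test_that("VEGF production needs producers, prefers hypoxia, and weights fibroblasts tenfold", {
  p <- defaultParameters()
  expect_identical(vegfProductionRate(0, 0, 0.1, p), 0)
  cs <- percentToNondim(seq(0.1, 21, length.out = 50))
  r <- vegfProductionRate(rep(0.2, 50), 0, cs, p)
  expect_true(all(diff(r) <= 0))  # inversely correlated with oxygen
  x <- 0.13
  for (c0 in percentToNondim(c(0.5, 3.7, 21)))
    expect_equal(vegfProductionRate(0, x, c0, p) /
                 vegfProductionRate(x, 0, c0, p), 10)
})

test_that("uniform reaction-free fields are a fixed point of the stepper", {
  cfg <- small_cfg()
  p <- defaultParameters()
  fld <- uniform_fields(21, 21, oxygen = 0.15)
  out <- stepFields(fld, NULL, NULL, cfg, p)
  expect_equal(max(abs(oxygenField(out) - 0.15)), 0, tolerance = 1e-12)
  expect_identical(simTime(out), cfg@dt)
})

test_that("cellular consumption strictly drains total oxygen", {
  cfg <- small_cfg()
  fld <- uniform_fields(21, 21, oxygen = 0.15, cells = 0.1)
  tot0 <- sum(oxygenField(fld))
  for (i in 1:10) fld <- stepFields(fld, NULL, NULL, cfg, defaultParameters())
  expect_lt(sum(oxygenField(fld)), tot0)
})

test_that("a single bead injects exactly dt times its release rate", {
  cfg <- small_cfg(bead_type = "HOG", bead_fraction = 1 / 441)
  p <- defaultParameters()
  fld <- uniform_fields(21, 21, oxygen = 0.05)
  beads <- placeBeads(21, 21, 1 / 441, "HOG", seed = 2, p)
  expect_identical(nBeads(beads), 1L)
  site <- beadSites(beads)[1, ]
  rate <- beadReleaseRate(oxygenField(fld)[site[1], site[2]], 0,
                          beadParams("HOG", p))
  out <- stepFields(fld, beads, NULL, cfg, p)
  gain <- sum(oxygenField(out)) - sum(oxygenField(fld))
  expect_equal(gain, cfg@dt * rate, tolerance = 1e-10)
})

test_that("boundary conditions clamp cells for three days and oxygen throughout", {
  cfg <- small_cfg()
  p <- defaultParameters()
  fld <- initializeFields(cfg, p)
  fld@t <- 1
  out <- applyBoundaryConditions(fld, cfg, p)
  m <- progenitorField(out)
  expect_true(all(c(m[1, ], m[21, ], m[, 1], m[, 21]) == 0.01))
  expect_true(all(oxygenField(out)[1, ] == p@c_host))

  fld@t <- 5
  fld@progenitor[] <- 0.25
  out <- applyBoundaryConditions(fld, cfg, p)
  expect_true(all(progenitorField(out)[1, ] == 0.25))  # mirror regime
  expect_true(all(oxygenField(out)[, 1] == p@c_host))
})

test_that("pure diffusion conserves every field over 1000 steps", {
  cfg <- small_cfg()
  p <- diffusion_only_params()
  set.seed(42)
  fld <- new("ContinuumFields",
             oxygen = matrix(runif(441, 0, 0.3), 21),
             vegf = matrix(runif(441, 0, 1), 21),
             progenitor = matrix(runif(441, 0, 0.2), 21),
             fibroblast = matrix(runif(441, 0, 0.2), 21),
             fibrous = matrix(runif(441, 0, 0.2), 21), t = 0)
  tot0 <- c(sum(fld@oxygen), sum(fld@vegf), sum(fld@progenitor),
            sum(fld@fibroblast), sum(fld@fibrous))
  for (i in 1:1000) fld <- stepFields(fld, NULL, NULL, cfg, p)
  tot1 <- c(sum(fld@oxygen), sum(fld@vegf), sum(fld@progenitor),
            sum(fld@fibroblast), sum(fld@fibrous))
  expect_equal(tot1, tot0, tolerance = 1e-10)
  expect_true(all(oxygenField(fld) >= 0))
})

test_that("HOG beads can only raise the oxygen field pointwise", {
  cfg0 <- small_cfg(seed = 5)
  cfgB <- small_cfg(seed = 5, bead_type = "HOG", bead_fraction = 0.02)
  p <- defaultParameters()
  f0 <- initializeFields(cfg0, p)
  fB <- initializeFields(cfgB, p)
  beads <- placeBeads(21, 21, 0.02, "HOG", cfgB@seed, p)
  for (i in 1:200) {
    f0 <- applyBoundaryConditions(f0, cfg0, p)
    fB <- applyBoundaryConditions(fB, cfgB, p)
    f0 <- stepFields(f0, NULL, NULL, cfg0, p)
    fB <- stepFields(fB, beads, NULL, cfgB, p)
    expect_true(all(oxygenField(fB) >= oxygenField(f0) - 1e-12))
  }
})

test_that("an unstable time step aborts with a message naming dt", {
  cfg <- small_cfg()
  slot(cfg, "dt", check = FALSE) <- 0.05  # far beyond dx^2/(4 Dmax)
  fld <- new("ContinuumFields",
             oxygen = matrix(runif(441, 0, 0.3), 21),
             vegf = matrix(0, 21, 21), progenitor = matrix(0.1, 21, 21),
             fibroblast = matrix(0, 21, 21), fibrous = matrix(0.1, 21, 21),
             t = 0)
  expect_error({
    for (i in 1:500) fld <- stepFields(fld, NULL, NULL, cfg,
                                       defaultParameters())
  }, "dt")
})
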