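test_that("anoxic fraction counts sites below the anoxia bound", {
  expect_identical(anoxicFraction(matrix(percentToNondim(3.7), 5, 5)), 0)
  expect_identical(anoxicFraction(matrix(percentToNondim(0.1), 5, 5)), 1)
  half <- matrix(percentToNondim(c(0.1, 3.7)), 4, 5)
  expect_identical(anoxicFraction(half), 0.5)
  expect_identical(hypoxicFraction(half), 0.5)
})

test_that("penetration depth measures the deepest vessel agent in mm", {
  cfg <- scenarioConfig(grid_nx = 101, grid_ny = 101, dx = 0.04)
  expect_identical(penetrationDepth(empty_network(101, 101), cfg), 0)
  edge <- agents_at(cbind(1L, 30L), A = 0, 101, 101)
  expect_identical(penetrationDepth(edge, cfg), 0)
  centre <- agents_at(cbind(51L, 51L), A = 0, 101, 101)
  expect_equal(penetrationDepth(centre, cfg), 2.0)
  expect_true(fullThickness(centre, cfg))
  expect_false(fullThickness(edge, cfg))
})

test_that("identical configuration and seed reproduce byte-identical metrics", {
  cfg <- small_cfg(bead_type = "HOG", bead_fraction = 0.02, t_end = 1,
                   seed = 3)
  r1 <- runScenario(cfg)
  r2 <- runScenario(cfg)
  expect_identical(metricsTable(r1), metricsTable(r2))
  expect_identical(agentSites(r1@network), agentSites(r2@network))
  cfg2 <- small_cfg(bead_type = "HOG", bead_fraction = 0.02, t_end = 1,
                    seed = 4)
  expect_false(identical(beadSites(placeBeads(21, 21, 0.02, "HOG", 3)),
                         beadSites(placeBeads(21, 21, 0.02, "HOG", 4))))
  expect_false(identical(metricsTable(runScenario(cfg2)),
                         metricsTable(r1)))
})

test_that("simulation metrics respect their structural invariants", {
  cfg <- small_cfg(bead_type = "CPO", bead_fraction = 0.02, t_end = 2)
  res <- runScenario(cfg)
  mt <- metricsTable(res)
  expect_true(all(diff(mt$time) > 0))
  expect_true(all(mt$anoxic_fraction >= 0 & mt$anoxic_fraction <= 1))
  expect_true(all(mt$anoxic_fraction + mt$hypoxic_fraction <= 1 + 1e-12))
  halfw <- cfg@dx * 21 / 2
  expect_true(all(mt$penetration_depth <= halfw))
  expect_true(validObject(res))
})

test_that("the CPO source is largely depleted after three days", {
  # the decay clock alone caps the day-3 source at exp(-0.5 * 3) ~ 0.223
  # of its time-zero value at matched oxygen
  cfg <- small_cfg(bead_type = "CPO", bead_fraction = 0.02, t_end = 3)
  p <- defaultParameters()
  res <- runScenario(cfg)
  beads <- placeBeads(21, 21, 0.02, "CPO", cfg@seed, p)
  bs <- beadSites(beads)
  c_day3 <- oxygenField(res)[bs]
  rate3 <- mean(beadReleaseRate(c_day3, 3, beadParams("CPO", p)))
  rate0_matched <- mean(beadReleaseRate(c_day3, 0, beadParams("CPO", p)))
  expect_lt(rate3, 0.25 * rate0_matched)
  expect_equal(rate3 / rate0_matched, exp(-1.5), tolerance = 1e-12)
  # by contrast a HOG source retains most of its strength at day 3
  expect_gt(beadReleaseRate(0, 3, beadParams("HOG", p)) / 2.2, 0.8)
})

test_that("condition sweeps aggregate replicates and flag inconsistency", {
  cfg <- small_cfg(t_end = 1, n_replicates = 2L, seed = 1)
  sw <- runConditionSweep(cfg, fractions = 0.02)
  expect_identical(sort(unique(sw$summary$bead_type)),
                   c("CPO", "HOG", "none"))
  expect_identical(nrow(sw$replicates), 6L)   # 3 conditions x 2 seeds
  expect_true(all(c("median", "q25", "q75", "cv", "consistent") %in%
                  names(sw$summary)))
  expect_true(all(sw$summary$q25 <= sw$summary$median + 1e-12))
  # n_replicates = 1: consistency is vacuously true
  sw1 <- runConditionSweep(small_cfg(t_end = 0.5), fractions = 0.02,
                           n_replicates = 1L)
  expect_true(all(sw1$summary$consistent))
  expect_true(all(sw1$summary$cv == 0))
})

test_that("an invalid scenario is refused before any stepping", {
  cfg <- small_cfg()
  slot(cfg, "dt", check = FALSE) <- 0.5
  expect_error(runScenario(cfg), "stability")
})
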