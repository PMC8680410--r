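test_that("boundary sprout seeding is deterministic and covers all sides", {
  cfg <- scenarioConfig()  # 100 x 100, spacing 10
  net <- seedBoundarySprouts(cfg)
  expect_identical(nAgents(net), 40L)       # 396 perimeter sites / 10
  expect_true(all(agentRoles(net) == "quiescent"))
  s <- agentSites(net)
  on_edge <- s[, 1] == 1 | s[, 1] == 100 | s[, 2] == 1 | s[, 2] == 100
  expect_true(all(on_edge))
  expect_true(any(s[, 1] == 1) && any(s[, 1] == 100) &&
              any(s[, 2] == 1) && any(s[, 2] == 100))
  expect_identical(boundaryRoots(net), seq_len(40L))
  net2 <- seedBoundarySprouts(cfg)
  expect_identical(agentSites(net2), s)     # determinism

  p <- defaultParameters()
  p@sprout_seed_spacing <- 101
  expect_error(seedBoundarySprouts(cfg, p), "spacing")
})

test_that("the all-zero Notch state at zero VEGF is a fixed point", {
  z <- setNames(rep(0, 8), colnames(agentState(makeEcRow(1))))
  out <- z
  for (i in 1:100) out <- notchStep(out, vegf = 0, dt = 0.002)
  expect_identical(unname(out), rep(0, 8))
  expect_error(notchStep(z, 1, dt = -0.01), ">= 0")
})

test_that("an isolated agent never activates Notch and stays nonnegative", {
  net <- makeEcRow(1)
  p <- defaultParameters()
  g <- matrix(0.8, 3, 3)
  for (i in 1:2000) {
    net <- notchStepNetwork(net, g, p, 0.002)
    st <- agentState(net)
    expect_true(all(st >= 0))
    expect_identical(unname(st[1, c("N", "Na", "Ne")] [2:3]), c(0, 0))
  }
  # actin converges towards the effective receptor activity
  expect_gt(agentState(net)[1, "A"], p@theta_tip)
})

test_that("two adjacent agents break symmetry towards the high-VEGFR cell", {
  p <- defaultParameters()
  net <- makeEcRow(2, perturbation = 1e-3)   # agent 1 gets +, agent 2 gets -
  expect_gt(agentState(net)[1, "V"], agentState(net)[2, "V"])
  net <- relax_notch(net, vegf_level = 1, p = p)
  A <- agentState(net)[, "A"]
  expect_identical(sum(A >= p@theta_tip), 1L)      # exactly one above theta
  expect_gt(A[1], A[2])                            # the high-V agent wins
  net <- selectTips(net, matrix(1, 3, 4), p)
  expect_identical(agentRoles(net), c("tip", "quiescent"))
})

test_that("a row of agents under uniform VEGF yields salt-and-pepper tips", {
  p <- defaultParameters()
  net <- makeEcRow(10, perturbation = 1e-3, seed = 4)
  net <- relax_notch(net, vegf_level = 1, p = p)
  net <- selectTips(net, matrix(1, 3, 12), p)
  tips <- which(agentRoles(net) == "tip")
  expect_gte(length(tips), 3)           # an alternating-type pattern
  expect_true(all(diff(tips) >= 2))     # no two adjacent tips
})

test_that("no two adjacent tips arise from any fuzzed actin state", {
  p <- defaultParameters()
  set.seed(123)
  for (trial in 1:1000) {
    n_sites <- sample(3:12, 1)
    idx <- sample(25, n_sites)
    sites <- cbind(((idx - 1L) %% 5L) + 1L, ((idx - 1L) %/% 5L) + 1L)
    # discrete levels force ties; the id rule must still break them
    A <- sample(c(0, 0.1, 0.2, 0.2, 0.5, 1), n_sites, replace = TRUE)
    net <- agents_at(sites, A, 5, 5)
    net <- selectTips(net, NULL, p)
    tips <- which(agentRoles(net) == "tip")
    if (length(tips) > 1) {
      ts <- agentSites(net)[tips, , drop = FALSE]
      dmat <- abs(outer(ts[, 1], ts[, 1], "-")) +
        abs(outer(ts[, 2], ts[, 2], "-"))
      expect_true(all(dmat[upper.tri(dmat)] > 1))
    }
  }
})

test_that("a tip climbs a linear VEGF gradient and stalls without error when boxed in", {
  p <- defaultParameters()
  cfg <- scenarioConfig(grid_nx = 11, grid_ny = 11)
  g <- makeVegfGradient(11, 11, "east", 1)
  net <- agents_at(cbind(6L, 2L), A = 0.5, 11, 11, role = "tip")
  for (i in 1:8) {
    before <- max(agentSites(net)[, 2])
    net <- growAndAnastomose(net, g, cfg, p)
    expect_identical(max(agentSites(net)[, 2]), before + 1L)  # strictly east
  }
  expect_identical(nAgents(net), 9L)
  expect_identical(nSegments(net), 8L)

  # boxed-in tip: all four neighbours occupied
  sq <- rbind(c(5L, 5L), c(6L, 4L), c(6L, 6L), c(7L, 5L), c(6L, 5L))
  boxed <- agents_at(sq, A = 0.5, 11, 11)
  boxed@role <- c(rep("stalk", 4), "tip")
  out <- growAndAnastomose(boxed, g, cfg, p)
  expect_identical(nAgents(out), 5L)              # stalled, nothing added
  expect_identical(agentRoles(out)[5], "tip")
})

test_that("head-on sprouts fuse into a perfused boundary-to-boundary loop", {
  p <- defaultParameters()
  cfg <- scenarioConfig(grid_nx = 9, grid_ny = 12)
  # two sprouts rooted on opposite edges of row 5, growing towards the
  # centre of a field peaked mid-domain
  g <- outer(rep(1, 9), -abs(seq_len(12) - 6.25))
  g <- g - min(g)
  net <- agents_at(rbind(c(5L, 1L), c(5L, 12L)), A = 0.5, 9, 12,
                   role = "tip")
  net@boundary_roots <- c(1L, 2L)
  for (i in 1:16) net <- growAndAnastomose(net, g, cfg, p)
  expect_gt(sum(perfusedSegments(net)), 0)
  expect_identical(tipCount(net), 0L)             # both tips retired
  # the perfused segments form a path whose endpoints are the roots
  pseg <- segments(net)[perfusedSegments(net), , drop = FALSE]
  gr <- igraph::make_graph(t(pseg), n = nAgents(net), directed = FALSE)
  deg <- igraph::degree(gr)
  ends <- which(deg == 1)
  expect_setequal(ends, boundaryRoots(net))
  expect_true(igraph::are_adjacent(
    igraph::make_graph(t(segments(net)), n = nAgents(net),
                       directed = FALSE), 1, 2) ||
    igraph::distances(gr, 1, 2) < Inf)
})

test_that("mirroring the VEGF field mirrors the grown network", {
  p <- defaultParameters()
  cfg <- scenarioConfig(grid_nx = 11, grid_ny = 11)
  ge <- makeVegfGradient(11, 11, "east", 1) +
    outer(seq_len(11) / 100, rep(1, 11))  # break N/S ties, no E/W ties
  gw <- ge[, 11:1]
  ne <- agents_at(cbind(6L, 1L), A = 0.5, 11, 11, role = "tip")
  nw <- agents_at(cbind(6L, 11L), A = 0.5, 11, 11, role = "tip")
  for (i in 1:6) {
    ne <- growAndAnastomose(ne, ge, cfg, p)
    nw <- growAndAnastomose(nw, gw, cfg, p)
  }
  se <- agentSites(ne); sw <- agentSites(nw)
  expect_identical(se[, 1], sw[, 1])
  expect_identical(12L - se[, 2], sw[, 2])
})

test_that("growth conserves agents and keeps at most one tip per sprout", {
  cfg <- small_cfg(bead_type = "HOG", bead_fraction = 0.02, t_end = 2)
  res <- runScenario(cfg)
  net <- res@network
  expect_gte(nAgents(net), 8L)  # seeds never deleted, growth added more
  sp_tips <- table(net@sprout_id[agentRoles(net) == "tip"])
  expect_true(all(sp_tips <= 1))
  expect_lte(tipCount(net), length(unique(net@sprout_id)))
})

test_that("perfused segments always lie on boundary-root loops", {
  cfg <- small_cfg(bead_type = "HOG", bead_fraction = 0.04, t_end = 3,
                   seed = 2)
  net <- runScenario(cfg)@network
  if (any(perfusedSegments(net))) {
    pseg <- segments(net)[perfusedSegments(net), , drop = FALSE]
    gr <- igraph::make_graph(t(pseg), n = nAgents(net), directed = FALSE)
    deg <- igraph::degree(gr)
    # every endpoint (degree-1 vertex) of the perfused subnetwork is a
    # boundary root, i.e. each perfused path runs root-to-root
    expect_true(all(which(deg == 1) %in% boundaryRoots(net)))
    comp <- igraph::components(gr)
    for (k in which(comp$csize > 1)) {
      members <- which(comp$membership == k & deg > 0)
      expect_gte(sum(members %in% boundaryRoots(net)), 2)
    }
  } else {
    succeed("no anastomosis occurred in this short window")
  }
})
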