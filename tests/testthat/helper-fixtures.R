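# Shared fixtures: small lattices keep the unit suite fast; the
# acceptance suite runs the full 100 x 100 implant.

small_cfg <- function(...) {
  scenarioConfig(grid_nx = 21L, grid_ny = 21L, ...)
}

# Zero out every reaction/source term so only diffusion remains.
diffusion_only_params <- function() {
  p <- defaultParameters()
  p@k_consume <- 0; p@r_prolif <- 0; p@d_anoxic <- 0
  p@r_matrix <- 0; p@lambda_vegf <- 0; p@u_ec <- 0
  p@p_vegf_progenitor <- 0
  p
}

# Uniform fields with chosen levels (bypasses initializeFields so tests
# can set cell density independently).
uniform_fields <- function(nx, ny, oxygen, cells = 0, vegf = 0,
                           fibro = 0, matrixf = 0, t = 0) {
  mk <- function(v) matrix(v, nx, ny)
  new("ContinuumFields", oxygen = mk(oxygen), vegf = mk(vegf),
      progenitor = mk(cells), fibroblast = mk(fibro),
      fibrous = mk(matrixf), t = t)
}

empty_network <- function(nx = 11L, ny = 11L) {
  new("VascularNetwork",
      sites = matrix(0L, 0, 2), role = character(0),
      state = matrix(0, 0, 8, dimnames = list(NULL, oxybeads:::.STATE_NAMES)),
      sprout_id = integer(0), segments = matrix(0L, 0, 2),
      perfused = logical(0), boundary_roots = integer(0),
      grid_nx = as.integer(nx), grid_ny = as.integer(ny))
}

# A network of agents at given sites (each its own sprout), with a
# prescribed actin level, for tip-selection tests.
agents_at <- function(sites, A, nx, ny, role = "quiescent") {
  n <- nrow(sites)
  state <- matrix(0, n, 8, dimnames = list(NULL, oxybeads:::.STATE_NAMES))
  state[, "A"] <- rep_len(A, n)
  new("VascularNetwork",
      sites = sites, role = rep(role, n), state = state,
      sprout_id = seq_len(n), segments = matrix(0L, 0, 2),
      perfused = logical(0), boundary_roots = integer(0),
      grid_nx = as.integer(nx), grid_ny = as.integer(ny))
}

# Integrate the Notch dynamics of a network under a constant uniform
# VEGF level until (near) steady state.
relax_notch <- function(net, vegf_level, p = defaultParameters(),
                        days = 8, dt = 0.002) {
  g <- matrix(vegf_level, net@grid_nx, net@grid_ny)
  for (i in seq_len(round(days / dt)))
    net <- notchStepNetwork(net, g, p, dt)
  net
}
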