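#' @include AllClasses.R AllGenerics.R bead-release.R vascular.R
NULL

#' Construct a synthetic fixture specification
#'
#' @param kind fixture kind: `"release_curve"`, `"vegf_field"`,
#'   `"ec_row"` or `"bead_layout"`.
#' @param params kind-specific named list, matching the arguments of
#'   the corresponding generator ([makeReleaseCurve()],
#'   [makeVegfGradient()], [makeEcRow()], [placeBeads()]).
#' @param seed integer seed; fixes the output exactly.
#' @param noise_sd nonnegative noise level; 0 gives the noiseless
#'   model output.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(kind, params = list(), seed = 1L, noise_sd = 0) {
  new("SyntheticSpec", kind = kind, params = params,
      seed = as.integer(seed), noise_sd = noise_sd)
}

#' @rdname generateSynthetic
setMethod("generateSynthetic", "SyntheticSpec", function(spec) {
  args <- spec@params
  switch(spec@kind,
    release_curve = do.call(makeReleaseCurve,
      c(args, list(seed = spec@seed, noise_sd = spec@noise_sd))),
    vegf_field = do.call(makeVegfGradient, args),
    ec_row = do.call(makeEcRow, c(args, list(seed = spec@seed))),
    bead_layout = do.call(placeBeads, c(args, list(seed = spec@seed))))
})

#' Generate a synthetic oxygen release curve
#'
#' Emulates a measured bead oxygen-generation time course: the release
#' law evaluated at zero ambient oxygen (the nitrogen-purged sensor
#' protocol), a CPO-like fast-decaying burst (`tau = 0.5`/day) or a
#' HOG-like sustained two-week release (`tau = 0.05`/day), plus
#' centred additive Gaussian noise clipped at zero. With
#' `noise_sd = 0` the curve equals the analytic model exactly, for any
#' seed.
#'
#' @param times sampling times (days), strictly increasing, nonempty.
#' @param G_n,tau,H_n,hill_h release parameters of the generating law.
#' @param oxygen ambient nondimensional oxygen of the recording
#'   (default 0).
#' @param noise_sd additive noise standard deviation.
#' @param seed integer seed for the noise.
#' @return a [ReleaseCurve-class].
#' @examples
#' hog <- makeReleaseCurve(0:14, G_n = 2.2, tau = 0.05)
#' releaseRates(hog)[15] / 2.2  # ~0.5: half the peak near two weeks
#' @export
makeReleaseCurve <- function(times, G_n = 2.2, tau = 0.05, H_n = 0.11,
                             hill_h = 6, oxygen = 0, noise_sd = 0,
                             seed = 1L) {
  if (length(times) == 0) stop("sampling times must be nonempty")
  params <- list(G_n = G_n, H_n = H_n, hill_h = hill_h, tau = tau)
  oxy <- rep_len(oxygen, length(times))
  rates <- beadReleaseRate(oxy, times, params)
  if (noise_sd > 0) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    rates <- pmax(rates + stats::rnorm(length(rates), 0, noise_sd), 0)
  }
  new("ReleaseCurve", times = as.numeric(times), rates = rates,
      oxygen = oxygen, noise_sd = noise_sd)
}

#' Generate a linear VEGF gradient field
#'
#' A linear ramp from 0 to `peak` along a compass direction, used as a
#' fixture for tip-migration tests.
#'
#' @param nx,ny lattice dimensions.
#' @param direction `"east"` (increasing column), `"west"`, `"south"`
#'   (increasing row) or `"north"`.
#' @param peak maximum value, `>= 0`.
#' @return an `nx x ny` numeric matrix.
#' @examples
#' makeVegfGradient(3, 3, "east", 1)
#' @export
makeVegfGradient <- function(nx, ny,
                             direction = c("east", "west", "south", "north"),
                             peak = 1) {
  direction <- match.arg(direction)
  if (peak < 0) stop("peak must be >= 0")
  ramp_col <- function(n) if (n == 1) 0 else (seq_len(n) - 1) / (n - 1)
  switch(direction,
    east = matrix(peak * ramp_col(ny), nx, ny, byrow = TRUE),
    west = matrix(peak * rev(ramp_col(ny)), nx, ny, byrow = TRUE),
    south = matrix(peak * ramp_col(nx), nx, ny),
    north = matrix(peak * rev(ramp_col(nx)), nx, ny))
}

#' Generate a row of endothelial agents for tip-selection tests
#'
#' A 1 x `n_cells` row of quiescent agents with identical baseline
#' intracellular state, plus seeded uniform perturbations of magnitude
#' `perturbation` on the VEGFR-2 level, which seed the symmetry
#' breaking of lateral inhibition. Each agent roots its own sprout.
#' For `n_cells = 2` the perturbation is applied antisymmetrically
#' (+/- `perturbation`), the canonical two-cell competition fixture.
#'
#' @param n_cells number of agents, `>= 1`.
#' @param perturbation perturbation magnitude on `V`.
#' @param seed integer seed for the perturbation pattern.
#' @param baseline_V baseline VEGFR-2 level.
#' @return a [VascularNetwork-class] on a `3 x (n_cells + 2)` lattice
#'   (one ghost ring so growth tests have room).
#' @export
makeEcRow <- function(n_cells, perturbation = 0, seed = 1L,
                      baseline_V = 0.5) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  n_cells <- as.integer(n_cells)
  state <- matrix(0, n_cells, 8, dimnames = list(NULL, .STATE_NAMES))
  state[, "V"] <- baseline_V
  if (perturbation > 0) {
    if (n_cells == 2L) {
      delta <- c(perturbation, -perturbation)
    } else {
      has_seed <- exists(".Random.seed", envir = globalenv(),
                         inherits = FALSE)
      if (has_seed) old <- get(".Random.seed", envir = globalenv())
      on.exit(if (has_seed) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
      delta <- stats::runif(n_cells, -perturbation, perturbation)
    }
    state[, "V"] <- pmax(state[, "V"] + delta, 0)
  }
  sites <- cbind(rep(2L, n_cells), seq_len(n_cells) + 1L)
  new("VascularNetwork",
      sites = sites, role = rep("quiescent", n_cells), state = state,
      sprout_id = seq_len(n_cells), segments = matrix(0L, 0, 2),
      perfused = logical(0), boundary_roots = integer(0),
      grid_nx = 3L, grid_ny = n_cells + 2L)
}
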