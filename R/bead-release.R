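#' @include AllClasses.R
NULL

#' Release parameters for a bead type
#'
#' Convenience bundle of the release-law constants (`G_n`, `H_n`,
#' `hill_h`, `tau`) for a given bead type. CPO and HOG beads share the
#' peak rate and oxygen half-saturation and differ only in the decay
#' rate `tau`.
#'
#' @param bead_type `"CPO"` or `"HOG"`.
#' @param p a [ModelParameters-class].
#' @return named list with `G_n`, `H_n`, `hill_h`, `tau`.
#' @examples
#' beadParams("HOG")$tau  # 0.05
#' @export
beadParams <- function(bead_type = c("CPO", "HOG"), p = defaultParameters()) {
  bead_type <- match.arg(bead_type)
  list(G_n = p@G_n, H_n = p@H_n, hill_h = p@hill_h,
       tau = if (bead_type == "CPO") p@tau_cpo else p@tau_hog)
}

#' Instantaneous bead oxygen-release rate
#'
#' The oxygen-gated, exponentially decaying release law
#' \deqn{r(c, t) = G_n \frac{H_n^h}{c^h + H_n^h} e^{-\tau t},}
#' with `c` the local nondimensional oxygen and `h` the Hill
#' coefficient (default 6). The decreasing Hill gate makes release
#' self-limiting: a bead in an already-oxygenated neighbourhood releases
#' little, so the bead field drives tissue towards (and not past) the
#' half-saturation tension `H_n`.
#'
#' @param c local nondimensional oxygen (vectorized), `>= 0`.
#' @param t time since implantation (days, vectorized), `>= 0`.
#' @param params release parameters, e.g. from [beadParams()].
#' @return nondimensional release rate(s), in `[0, G_n]`.
#' @examples
#' beadReleaseRate(0, 0, beadParams("CPO"))      # 2.2
#' beadReleaseRate(0.11, 0, beadParams("CPO"))   # 1.1 (half-saturation)
#' @export
beadReleaseRate <- function(c, t, params = beadParams("CPO")) {
  if (any(c < 0)) stop("local oxygen must be >= 0")
  if (any(t < 0)) stop("time must be >= 0")
  with(params, G_n * H_n^hill_h / (c^hill_h + H_n^hill_h) * exp(-tau * t))
}

#' Cumulative release at zero oxygen, in closed form
#'
#' At `c = 0` the Hill gate is 1 and the release law integrates to
#' `(G_n / tau) (1 - exp(-tau t))`; its `t -> Inf` limit, `G_n / tau`,
#' is the total oxygen budget of a bead. The tenfold `tau` ratio between
#' CPO and HOG hence gives HOGs a tenfold total budget.
#'
#' @param t time (days, vectorized), `>= 0`; `Inf` gives the budget.
#' @param params release parameters, e.g. from [beadParams()].
#' @return cumulative nondimensional release.
#' @examples
#' cumulativeReleaseZeroOxygen(Inf, beadParams("CPO"))  # 4.4
#' cumulativeReleaseZeroOxygen(Inf, beadParams("HOG"))  # 44
#' @export
cumulativeReleaseZeroOxygen <- function(t, params = beadParams("CPO")) {
  if (any(t < 0)) stop("time must be >= 0")
  if (params$tau == 0) stop("tau must be nonzero for the closed form")
  params$G_n / params$tau * (1 - exp(-params$tau * t))
}

#' Randomly place beads on the lattice
#'
#' Samples `round(fraction * nx * ny)` distinct lattice sites uniformly
#' without replacement. The placement is a pure function of
#' `(grid, fraction, seed)`; the caller's RNG state is left untouched.
#'
#' @param grid_nx,grid_ny lattice site counts.
#' @param fraction target occupied-site fraction in `[0, 1]`.
#' @param bead_type `"CPO"` or `"HOG"`.
#' @param seed integer placement seed.
#' @param p a [ModelParameters-class] supplying the release constants.
#' @return a [BeadSet-class].
#' @examples
#' nBeads(placeBeads(100, 100, 0.02, "HOG", seed = 1))  # 200
#' @export
placeBeads <- function(grid_nx, grid_ny, fraction,
                       bead_type = c("CPO", "HOG"), seed = 1L,
                       p = defaultParameters()) {
  bead_type <- match.arg(bead_type)
  if (fraction < 0 || fraction > 1)
    stop("bead fraction must lie in [0, 1]")
  grid_nx <- as.integer(grid_nx); grid_ny <- as.integer(grid_ny)
  n_total <- grid_nx * grid_ny
  n <- round(fraction * n_total)
  idx <- if (n > 0) {
    withCallingHandlers(
      local_seed_sample(n_total, n, seed),
      warning = function(w) invokeRestart("muffleWarning"))
  } else integer(0)
  sites <- cbind(row = ((idx - 1L) %% grid_nx) + 1L,
                 col = ((idx - 1L) %/% grid_nx) + 1L)
  bp <- beadParams(bead_type, p)
  new("BeadSet", sites = sites, bead_type = bead_type,
      G_n = bp$G_n, H_n = bp$H_n, hill_h = bp$hill_h, tau = bp$tau,
      placement_seed = as.integer(seed),
      grid_nx = grid_nx, grid_ny = grid_ny)
}

# Sample without replacement under a private RNG stream, restoring the
# caller's .Random.seed.
local_seed_sample <- function(n_total, n, seed) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  sort(sample.int(n_total, n, replace = FALSE))
}

#' Estimate release parameters from a release curve
#'
#' Nonlinear least squares (Levenberg-Marquardt, via
#' \pkg{minpack.lm}) of the release law against a sampled curve. With
#' `fixH = TRUE` (the default, appropriate for the standard zero-oxygen
#' release protocol) the peak rate `G_n` and decay rate `tau` are
#' estimated and `H_n` is taken from `params`. At zero ambient oxygen
#' the Hill gate is identically 1, so `H_n` is structurally
#' unidentifiable there; `fixH = FALSE` additionally estimates `H_n` and
#' therefore requires a curve recorded at non-zero oxygen (the
#' `oxygen` slot of the curve).
#'
#' Initialization is deterministic: `G` starts at the maximum observed
#' rate and `tau` at the log-slope between the first and last strictly
#' positive points.
#'
#' @param curve a [ReleaseCurve-class] with at least 5 points.
#' @param fixH logical; keep `H_n` fixed (default `TRUE`).
#' @param params release parameters supplying the Hill constants, e.g.
#'   [beadParams()].
#' @return list with elements `G_n`, `tau`, `H_n`, `residual_norm`, and
#'   `fitted` (the fitted rates).
#' @examples
#' cv <- makeReleaseCurve(times = 0:13, G_n = 2.2, tau = 0.05)
#' fitReleaseParams(cv)$tau  # 0.05 (exact on noiseless data)
#' @export
fitReleaseParams <- function(curve, fixH = TRUE,
                             params = beadParams("CPO")) {
  stopifnot(is(curve, "ReleaseCurve"))
  tt <- curve@times; rr <- curve@rates
  oxy <- rep_len(curve@oxygen, length(tt))
  if (length(tt) < 5) stop("release curve must have at least 5 points")
  if (all(rr <= 0)) stop("degenerate release curve: all rates are zero")
  if (any(rr < 0)) stop("release rates must be >= 0")

  pos <- which(rr > 0)
  i1 <- pos[1]; i2 <- pos[length(pos)]
  G0 <- max(rr)
  tau0 <- if (i2 > i1 && rr[i1] != rr[i2])
    (log(rr[i1]) - log(rr[i2])) / (tt[i2] - tt[i1]) else 0.1
  tau0 <- max(tau0, 1e-3)
  h <- params$hill_h

  if (fixH) {
    H <- params$H_n
    hfac <- H^h / (oxy^h + H^h)
    fit <- minpack.lm::nlsLM(
      rr ~ G * hfac * exp(-tau * tt),
      start = list(G = G0, tau = tau0),
      lower = c(0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14))
    est <- stats::coef(fit)
    out <- list(G_n = unname(est["G"]), tau = unname(est["tau"]), H_n = H)
  } else {
    if (all(oxy == 0))
      stop("H_n is not identifiable from a zero-oxygen curve; ",
           "record the curve at non-zero oxygen or use fixH = TRUE")
    fit <- minpack.lm::nlsLM(
      rr ~ G * H^h / (oxy^h + H^h) * exp(-tau * tt),
      start = list(G = G0, tau = tau0, H = params$H_n),
      lower = c(0, 0, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14))
    est <- stats::coef(fit)
    out <- list(G_n = unname(est["G"]), tau = unname(est["tau"]),
                H_n = unname(est["H"]))
  }
  out$fitted <- as.numeric(stats::fitted(fit))
  out$residual_norm <- sqrt(sum((rr - out$fitted)^2))
  out
}
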