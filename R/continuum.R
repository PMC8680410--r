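#' @include AllClasses.R
#' @useDynLib oxybeads, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Initialize the continuum fields
#'
#' The implant starts at 3.7\% oxygen tension (nondimensional
#' `c_init = 3.7/21`), fibrous matrix 0.1, progenitor density 0.1, and
#' no fibroblasts or VEGF.
#'
#' @param cfg a [ScenarioConfig-class].
#' @param p a [ModelParameters-class].
#' @return a [ContinuumFields-class] at `t = 0`.
#' @examples
#' fld <- initializeFields(scenarioConfig(), defaultParameters())
#' oxygenToPercent(mean(oxygenField(fld)))  # 3.7
#' @export
initializeFields <- function(cfg, p = defaultParameters()) {
  mk <- function(v) matrix(v, cfg@grid_nx, cfg@grid_ny)
  new("ContinuumFields",
      oxygen = mk(p@c_init), vegf = mk(0),
      progenitor = mk(p@ic_msc), fibroblast = mk(0),
      fibrous = mk(p@ic_mf), t = 0)
}

#' Classify oxygen tension
#'
#' Anoxic below 0.5\% dissolved oxygen, hypoxic from 0.5\% up to 5\%,
#' normoxic above.
#'
#' @param c nondimensional oxygen (vectorized), `>= 0`.
#' @param p a [ModelParameters-class] supplying the thresholds.
#' @return character vector: `"anoxic"`, `"hypoxic"` or `"normoxic"`.
#' @examples
#' classifyOxygen(percentToNondim(c(0.3, 3.7, 21)))
#' @export
classifyOxygen <- function(c, p = defaultParameters()) {
  if (any(c < 0)) stop("oxygen must be >= 0")
  out <- rep("normoxic", length(c))
  out[c < p@c_hypoxia] <- "hypoxic"
  out[c < p@c_anoxia] <- "anoxic"
  out
}

#' Hypoxia-amplified VEGF production rate
#'
#' Per-site VEGF production
#' \deqn{(p_m m + 10 p_m f) \, \varphi(c), \qquad
#'   \varphi(c) = 1 + (\varphi_{max} - 1)
#'   \frac{K_\varphi^q}{c^q + K_\varphi^q},}
#' i.e. production scales with the producing cell densities (fibroblasts
#' ten times stronger than progenitors) and is amplified under low
#' oxygen, capturing the inverse correlation between oxygen tension and
#' total secreted VEGF. Dead tissue (`m = f = 0`) produces nothing
#' regardless of oxygen.
#'
#' @param m progenitor density (vectorized).
#' @param f fibroblast density.
#' @param c nondimensional oxygen.
#' @param p a [ModelParameters-class].
#' @return production rate(s), per day.
#' @export
vegfProductionRate <- function(m, f, c, p = defaultParameters()) {
  if (any(m < 0) || any(f < 0) || any(c < 0))
    stop("inputs must be >= 0")
  phi <- 1 + (p@phi_max - 1) * p@K_phi^p@q_phi /
    (c^p@q_phi + p@K_phi^p@q_phi)
  (p@p_vegf_progenitor * m +
     p@fibroblast_vegf_multiplier * p@p_vegf_progenitor * f) * phi
}

.ec_masks <- function(network, nx, ny) {
  ec <- matrix(FALSE, nx, ny)
  perf <- matrix(FALSE, nx, ny)
  if (!is.null(network) && nAgents(network) > 0) {
    s <- network@sites
    ec[cbind(s[, 1], s[, 2])] <- TRUE
    if (nrow(network@segments) > 0 && any(network@perfused)) {
      pseg <- network@segments[network@perfused, , drop = FALSE]
      pid <- unique(as.vector(pseg))
      perf[cbind(s[pid, 1], s[pid, 2])] <- TRUE
    }
  }
  list(ec = ec, perf = perf)
}

.step_par <- function(cfg, p) {
  list(dt = cfg@dt, inv_dx2 = 1 / cfg@dx^2,
       D_oxygen = p@D_oxygen, D_vegf = p@D_vegf, D_cell = p@D_cell,
       k_consume = p@k_consume, K_consume = p@K_consume,
       p_vegf_progenitor = p@p_vegf_progenitor,
       fibroblast_vegf_multiplier = p@fibroblast_vegf_multiplier,
       phi_max = p@phi_max, K_phi = p@K_phi, q_phi = p@q_phi,
       lambda_vegf = p@lambda_vegf, u_ec = p@u_ec,
       r_prolif = p@r_prolif, d_anoxic = p@d_anoxic,
       carrying_capacity = p@carrying_capacity, r_matrix = p@r_matrix,
       c_anoxia = p@c_anoxia, c_vessel = p@c_vessel,
       vessel_relax_rate = p@vessel_relax_multiplier * p@k_consume)
}

#' Advance the continuum fields by one explicit time step
#'
#' One synchronous explicit finite-difference step of the
#' taxis-diffusion-reaction system: oxygen diffuses, is consumed by
#' cells (Michaelis-Menten), released by beads (oxygen-gated decaying
#' sources) and delivered at perfused vessel sites (relaxation towards
#' `c_vessel`); VEGF diffuses, is produced by hypoxic tissue, decays
#' and is taken up at endothelial sites; progenitors and fibroblasts
#' diffuse and proliferate logistically with oxygen-limited rate
#' `c/(c + K)` and die in anoxia; fibrous matrix is deposited by cells.
#' Boundaries are zero-flux (ghost mirroring); Dirichlet conditions are
#' the job of [applyBoundaryConditions()]. Negative values are clipped
#' to zero.
#'
#' @param fields a [ContinuumFields-class].
#' @param beads a [BeadSet-class] or `NULL`.
#' @param network a [VascularNetwork-class] or `NULL`.
#' @param cfg a [ScenarioConfig-class].
#' @param p a [ModelParameters-class].
#' @return the updated [ContinuumFields-class] with `t` advanced by `dt`.
#' @export
stepFields <- function(fields, beads = NULL, network = NULL,
                       cfg = scenarioConfig(), p = defaultParameters()) {
  if (is.null(beads) || nBeads(beads) == 0) {
    brow <- integer(0); bcol <- integer(0)
    bG <- 0; bH <- 1; bh <- 1; btau <- 0
  } else {
    brow <- beads@sites[, 1]; bcol <- beads@sites[, 2]
    bG <- beads@G_n; bH <- beads@H_n; bh <- beads@hill_h; btau <- beads@tau
  }
  masks <- .ec_masks(network, nrow(fields@oxygen), ncol(fields@oxygen))
  upd <- .step_fields_cpp(fields@oxygen, fields@vegf, fields@progenitor,
                          fields@fibroblast, fields@fibrous,
                          as.integer(brow), as.integer(bcol),
                          bG, bH, bh, btau, fields@t,
                          masks$ec, masks$perf, .step_par(cfg, p))
  if (!upd$finite)
    stop(sprintf(
      "numerical instability (non-finite field) at t = %.4f; dt = %g violates the stability bound",
      fields@t, cfg@dt))
  new("ContinuumFields",
      oxygen = upd$oxygen, vegf = upd$vegf, progenitor = upd$progenitor,
      fibroblast = upd$fibroblast, fibrous = upd$fibrous,
      t = fields@t + cfg@dt)
}

#' Apply boundary conditions to the continuum fields
#'
#' Oxygen is clamped to the host tension `c_host` on the boundary ring
#' at all times. Progenitor and fibroblast densities are clamped to the
#' Dirichlet value 0.01 on the boundary while `t <= 3` days (cells
#' migrating in from the surrounding tissue); afterwards the cell
#' boundaries revert to the stepper's zero-flux ghost mirror. VEGF and
#' matrix are always zero-flux.
#'
#' @param fields a [ContinuumFields-class].
#' @param cfg a [ScenarioConfig-class].
#' @param p a [ModelParameters-class].
#' @return the updated [ContinuumFields-class].
#' @export
applyBoundaryConditions <- function(fields, cfg = scenarioConfig(),
                                    p = defaultParameters()) {
  nx <- nrow(fields@oxygen); ny <- ncol(fields@oxygen)
  ring <- function(mat, value) {
    mat[1, ] <- value; mat[nx, ] <- value
    mat[, 1] <- value; mat[, ny] <- value
    mat
  }
  fields@oxygen <- ring(fields@oxygen, p@c_host)
  if (fields@t <= p@bc_cell_duration) {
    fields@progenitor <- ring(fields@progenitor, p@bc_cell_value)
    fields@fibroblast <- ring(fields@fibroblast, p@bc_cell_value)
  }
  fields
}
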