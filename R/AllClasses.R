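#' @import methods
NULL

#' Model parameters for the self-oxygenating implant simulator
#'
#' Every rate, threshold and nondimensional constant of the coupled
#' tissue/vascular model lives here. Oxygen is nondimensional with
#' 1.0 equal to atmospheric normoxia (21\% dissolved oxygen), so the
#' hypoxia and anoxia thresholds of 5\% and 0.5\% map to 5/21 and 0.5/21.
#' Time is in days; lengths in mm; diffusivities in mm^2/day.
#'
#' Release-law constants: `G_n` (peak nondimensional release rate),
#' `H_n` (oxygen half-saturation of the Hill gate), `hill_h` (Hill
#' coefficient), and the release decay rates `tau_cpo`, `tau_hog`
#' (per day). CPO beads burn out within days (half-life
#' log(2)/0.5 ~ 1.4 d); HOGs sustain release for about two weeks
#' (log(2)/0.05 ~ 13.9 d).
#'
#' @slot G_n peak nondimensional bead release rate.
#' @slot H_n nondimensional oxygen half-saturation of release.
#' @slot hill_h Hill coefficient of the oxygen gate.
#' @slot tau_cpo,tau_hog release decay rates (per day).
#' @slot c_init,c_host,c_vessel nondimensional oxygen: initial implant
#'   tension, host/boundary tension, and the level a perfused vessel
#'   site is relaxed towards.
#' @slot c_anoxia,c_hypoxia nondimensional classification thresholds.
#' @slot D_oxygen,D_vegf,D_cell diffusivities (mm^2/day).
#' @slot k_consume max per-unit-cell oxygen consumption (per day).
#' @slot K_consume oxygen Michaelis constant of consumption.
#' @slot p_vegf_progenitor baseline VEGF production rate per unit
#'   progenitor density (per day).
#' @slot fibroblast_vegf_multiplier dimensionless fibroblast/progenitor
#'   VEGF production ratio (10).
#' @slot phi_max,K_phi,q_phi hypoxia amplification of VEGF production:
#'   phi(c) = 1 + (phi_max - 1) K_phi^q / (c^q + K_phi^q).
#' @slot lambda_vegf VEGF decay rate (per day).
#' @slot u_ec VEGF uptake rate per endothelial site (per day).
#' @slot r_prolif max proliferation rate (per day).
#' @slot d_anoxic anoxic death rate (per day).
#' @slot carrying_capacity nondimensional combined cell-density cap.
#' @slot r_matrix fibrous-matrix deposition rate (per day).
#' @slot ic_mf,ic_msc initial matrix / progenitor densities.
#' @slot bc_cell_value Dirichlet cell density on the boundary.
#' @slot bc_cell_duration days the cell Dirichlet condition is held.
#' @slot theta_tip actin threshold for tip selection.
#' @slot stalk_sensing fractional VEGF exposure of enclosed stalk cells
#'   relative to the filopodia-bearing sprout head.
#' @slot sprout_seed_spacing boundary sites between initial sprouts.
#' @slot growth_interval days between tip advances.
#' @slot vessel_relax_multiplier perfused-site oxygen delivery rate,
#'   as a multiple of `k_consume`.
#' @slot notch_alpha,notch_delta VEGF-gated production and first-order
#'   decay rates shared by the intracellular species (per day).
#' @slot K_vegf_gate VEGF half-saturation of receptor/Notch production.
#' @slot k_on VEGFR-2 activation rate per unit VEGF (per day).
#' @slot k_notch Notch1 activation rate per unit neighbour Dll4 (per day).
#' @slot dll4_max,K_dll4 Dll4 production: rate dll4_max Ve^2/(Ve^2+K_dll4^2).
#' @slot K_notch_inh effective-VEGFR attenuation scale:
#'   Ve = Va / (1 + (Ne/K_notch_inh)^2).
#'
#' @seealso [defaultParameters()], [validateConfig()]
#' @export
setClass("ModelParameters",
  slots = c(
    G_n = "numeric", H_n = "numeric", hill_h = "numeric",
    tau_cpo = "numeric", tau_hog = "numeric",
    c_init = "numeric", c_host = "numeric", c_vessel = "numeric",
    c_anoxia = "numeric", c_hypoxia = "numeric",
    D_oxygen = "numeric", D_vegf = "numeric", D_cell = "numeric",
    k_consume = "numeric", K_consume = "numeric",
    p_vegf_progenitor = "numeric", fibroblast_vegf_multiplier = "numeric",
    phi_max = "numeric", K_phi = "numeric", q_phi = "numeric",
    lambda_vegf = "numeric", u_ec = "numeric",
    r_prolif = "numeric", d_anoxic = "numeric",
    carrying_capacity = "numeric", r_matrix = "numeric",
    ic_mf = "numeric", ic_msc = "numeric",
    bc_cell_value = "numeric", bc_cell_duration = "numeric",
    theta_tip = "numeric", stalk_sensing = "numeric",
    sprout_seed_spacing = "numeric",
    growth_interval = "numeric", vessel_relax_multiplier = "numeric",
    notch_alpha = "numeric", notch_delta = "numeric",
    K_vegf_gate = "numeric", k_on = "numeric", k_notch = "numeric",
    dll4_max = "numeric", K_dll4 = "numeric", K_notch_inh = "numeric"
  ),
  prototype = prototype(
    G_n = 2.2, H_n = 0.11, hill_h = 6,
    tau_cpo = 0.5, tau_hog = 0.05,
    c_init = 3.7 / 21, c_host = 3.7 / 21, c_vessel = 6 / 21,
    c_anoxia = 0.5 / 21, c_hypoxia = 5 / 21,
    D_oxygen = 0.05, D_vegf = 0.05, D_cell = 0.005,
    k_consume = 2.0, K_consume = 0.2,
    p_vegf_progenitor = 1, fibroblast_vegf_multiplier = 10,
    phi_max = 5, K_phi = 2.5 / 21, q_phi = 4,
    lambda_vegf = 1, u_ec = 3,
    r_prolif = 0.3, d_anoxic = 1.5,
    carrying_capacity = 1, r_matrix = 0.2,
    ic_mf = 0.1, ic_msc = 0.1,
    bc_cell_value = 0.01, bc_cell_duration = 3,
    theta_tip = 0.15, stalk_sensing = 0.2, sprout_seed_spacing = 10,
    growth_interval = 0.1, vessel_relax_multiplier = 10,
    notch_alpha = 5, notch_delta = 5,
    K_vegf_gate = 0.1, k_on = 10, k_notch = 10,
    dll4_max = 5, K_dll4 = 0.3, K_notch_inh = 0.1
  )
)

setValidity("ModelParameters", function(object) {
  msg <- character(0)
  num <- vapply(slotNames(object), function(s) slot(object, s), numeric(1))
  if (any(!is.finite(num)))
    msg <- c(msg, "all parameters must be finite")
  nonneg <- setdiff(names(num), character(0))
  if (any(num[nonneg] < 0))
    msg <- c(msg, sprintf("negative parameter(s): %s",
                          paste(nonneg[num[nonneg] < 0], collapse = ", ")))
  if (!(object@c_anoxia < object@c_hypoxia && object@c_hypoxia < 1))
    msg <- c(msg, "thresholds must satisfy c_anoxia < c_hypoxia < 1")
  if (object@c_init > 1)
    msg <- c(msg, "c_init must lie in [0, 1]")
  if (object@hill_h < 1)
    msg <- c(msg, "hill_h must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Scenario configuration
#'
#' Describes one in-silico implantation: lattice geometry, duration,
#' bead condition and seeding. The implant is a square patch of
#' `grid_nx` x `grid_ny` lattice sites with physical spacing `dx` (mm);
#' the default 100 x 100 at 0.04 mm reproduces a 4 mm wide construct
#' followed for 7 days, the in vivo implantation window.
#'
#' @slot grid_nx,grid_ny lattice site counts.
#' @slot dx physical lattice spacing (mm).
#' @slot t_end simulated duration (days).
#' @slot dt explicit time step (days); must satisfy the diffusion
#'   stability bound dt <= dx^2 / (4 max(D)).
#' @slot bead_type one of `"none"`, `"CPO"`, `"HOG"`.
#' @slot bead_fraction fraction of lattice sites occupied by beads.
#' @slot seed integer seed for stochastic bead placement.
#' @slot n_replicates replicate count for sweeps.
#' @slot output_interval days between metric captures.
#' @export
setClass("ScenarioConfig",
  slots = c(
    grid_nx = "integer", grid_ny = "integer", dx = "numeric",
    t_end = "numeric", dt = "numeric",
    bead_type = "character", bead_fraction = "numeric",
    seed = "integer", n_replicates = "integer",
    output_interval = "numeric"
  ),
  prototype = prototype(
    grid_nx = 100L, grid_ny = 100L, dx = 0.04,
    t_end = 7, dt = 0.002,
    bead_type = "none", bead_fraction = 0,
    seed = 1L, n_replicates = 5L,
    output_interval = 0.25
  )
)

setValidity("ScenarioConfig", function(object) {
  msg <- character(0)
  if (!object@bead_type %in% c("none", "CPO", "HOG"))
    msg <- c(msg, "bead_type must be one of none, CPO, HOG")
  if (object@grid_nx < 3L || object@grid_ny < 3L)
    msg <- c(msg, "grid must be at least 3 x 3")
  if (object@dx <= 0 || object@dt <= 0 || object@t_end <= 0)
    msg <- c(msg, "dx, dt and t_end must be positive")
  if (object@bead_fraction < 0 || object@bead_fraction > 0.1)
    msg <- c(msg, "bead_fraction must lie in [0, 0.1]")
  if (length(msg)) msg else TRUE
})

#' A set of oxygen-generating beads on the lattice
#'
#' Bead positions are sampled uniformly without replacement at a target
#' area fraction; each bead is a volumetric oxygen source following the
#' oxygen-gated, exponentially decaying release law.
#'
#' @slot sites integer matrix (n x 2; columns row, col) of occupied sites.
#' @slot bead_type `"CPO"` or `"HOG"`.
#' @slot G_n,H_n,hill_h,tau the release parameters in effect.
#' @slot placement_seed integer seed that produced the layout.
#' @slot grid_nx,grid_ny lattice extent the sites live on.
#' @export
setClass("BeadSet",
  slots = c(
    sites = "matrix", bead_type = "character",
    G_n = "numeric", H_n = "numeric", hill_h = "numeric", tau = "numeric",
    placement_seed = "integer",
    grid_nx = "integer", grid_ny = "integer"
  )
)

setValidity("BeadSet", function(object) {
  msg <- character(0)
  s <- object@sites
  if (ncol(s) != 2) msg <- c(msg, "sites must have two columns (row, col)")
  if (nrow(s) > 0) {
    if (any(s[, 1] < 1 | s[, 1] > object@grid_nx |
            s[, 2] < 1 | s[, 2] > object@grid_ny))
      msg <- c(msg, "bead sites out of lattice bounds")
    if (anyDuplicated(s[, 1] + (s[, 2] - 1) * object@grid_nx))
      msg <- c(msg, "bead sites must be unique")
  }
  if (!object@bead_type %in% c("CPO", "HOG"))
    msg <- c(msg, "bead_type must be CPO or HOG")
  if (length(msg)) msg else TRUE
})

#' An oxygen release curve
#'
#' A sampled bead oxygen-generation time course, optionally recorded at
#' a non-zero ambient oxygen tension (needed if the Hill half-saturation
#' is to be estimated rather than fixed).
#'
#' @slot times sampling times (days), strictly increasing.
#' @slot rates nondimensional release rates.
#' @slot oxygen nondimensional ambient oxygen at which the curve was
#'   recorded (length 1 or length(times)); 0 for the standard
#'   zero-oxygen (nitrogen-purged) protocol.
#' @slot noise_sd nondimensional additive noise level used to generate
#'   the curve (0 for measured/noiseless curves).
#' @export
setClass("ReleaseCurve",
  slots = c(times = "numeric", rates = "numeric",
            oxygen = "numeric", noise_sd = "numeric"),
  prototype = prototype(oxygen = 0, noise_sd = 0)
)

setValidity("ReleaseCurve", function(object) {
  msg <- character(0)
  if (length(object@times) != length(object@rates))
    msg <- c(msg, "times and rates must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (!length(object@oxygen) %in% c(1L, length(object@times)))
    msg <- c(msg, "oxygen must have length 1 or length(times)")
  if (any(object@oxygen < 0)) msg <- c(msg, "oxygen must be >= 0")
  if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Gridded continuum fields of the tissue model
#'
#' The five tissue-level scalar fields on the scenario lattice: oxygen
#' `c`, VEGF `g`, progenitor cell density `m`, fibroblast density `f`
#' and fibrous matrix `mf`, plus the current simulation time.
#'
#' @slot oxygen,vegf,progenitor,fibroblast,fibrous numeric matrices of
#'   identical dimension, all nonnegative.
#' @slot t current time (days).
#' @export
setClass("ContinuumFields",
  slots = c(oxygen = "matrix", vegf = "matrix", progenitor = "matrix",
            fibroblast = "matrix", fibrous = "matrix", t = "numeric")
)

setValidity("ContinuumFields", function(object) {
  msg <- character(0)
  d <- dim(object@oxygen)
  for (s in c("vegf", "progenitor", "fibroblast", "fibrous"))
    if (!identical(dim(slot(object, s)), d))
      msg <- c(msg, sprintf("field %s has mismatched dimensions", s))
  for (s in c("oxygen", "vegf", "progenitor", "fibroblast", "fibrous")) {
    v <- slot(object, s)
    if (any(!is.finite(v))) msg <- c(msg, sprintf("field %s is non-finite", s))
    else if (any(v < 0)) msg <- c(msg, sprintf("field %s is negative", s))
  }
  if (length(msg)) msg else TRUE
})

.STATE_NAMES <- c("V", "Va", "Ve", "N", "Na", "Ne", "D4", "A")

#' A discrete vascular network of endothelial agents
#'
#' Endothelial cells occupy lattice sites (at most one per site), carry
#' an 8-species intracellular state (VEGFR-2 `V`, active VEGFR-2 `Va`,
#' effective active VEGFR-2 `Ve`, Notch1 `N`, active Notch1 `Na`,
#' effective active Notch1 `Ne`, Dll4 `D4`, actin `A`) and are connected
#' into sprouts by lattice-adjacent segments. Sprouts seeded on the
#' domain boundary grow inwards; a sprout fusing with a different sprout
#' (anastomosis) closes a loop between two boundary roots, whose
#' segments are then flagged perfused and deliver oxygen.
#'
#' @slot sites integer matrix (n x 2) of agent positions.
#' @slot role character vector: `"tip"`, `"stalk"` or `"quiescent"`.
#' @slot state numeric n x 8 matrix, columns `V, Va, Ve, N, Na, Ne, D4, A`.
#' @slot sprout_id integer sprout membership per agent.
#' @slot segments integer m x 2 matrix of agent indices (undirected).
#' @slot perfused logical per-segment perfusion flag.
#' @slot boundary_roots integer ids of the agents seeded on the boundary.
#' @slot grid_nx,grid_ny lattice extent.
#' @export
setClass("VascularNetwork",
  slots = c(
    sites = "matrix", role = "character", state = "matrix",
    sprout_id = "integer", segments = "matrix", perfused = "logical",
    boundary_roots = "integer", grid_nx = "integer", grid_ny = "integer"
  )
)

setValidity("VascularNetwork", function(object) {
  msg <- character(0)
  n <- nrow(object@sites)
  if (length(object@role) != n || nrow(object@state) != n ||
      length(object@sprout_id) != n)
    msg <- c(msg, "role, state and sprout_id must match the agent count")
  if (n > 0 && anyDuplicated(object@sites[, 1] +
                             (object@sites[, 2] - 1) * object@grid_nx))
    msg <- c(msg, "at most one agent per lattice site")
  if (ncol(object@state) != 8)
    msg <- c(msg, "state must have 8 columns")
  if (any(object@state < 0)) msg <- c(msg, "intracellular state must be >= 0")
  if (!all(object@role %in% c("tip", "stalk", "quiescent")))
    msg <- c(msg, "roles must be tip, stalk or quiescent")
  m <- nrow(object@segments)
  if (length(object@perfused) != m)
    msg <- c(msg, "perfused flags must match the segment count")
  if (m > 0) {
    if (any(object@segments < 1 | object@segments > n))
      msg <- c(msg, "segment endpoints must be agent indices")
    dr <- abs(object@sites[object@segments[, 1], 1] -
              object@sites[object@segments[, 2], 1])
    dc <- abs(object@sites[object@segments[, 1], 2] -
              object@sites[object@segments[, 2], 2])
    if (any(dr + dc != 1))
      msg <- c(msg, "segments must connect lattice-adjacent sites")
  }
  if (length(msg)) msg else TRUE
})

#' Result of one simulated implantation scenario
#'
#' @slot config the [ScenarioConfig-class] that was run (echoed for
#'   provenance).
#' @slot params the [ModelParameters-class] in effect.
#' @slot metrics per-timepoint data.frame of implant metrics: time,
#'   anoxic_fraction, hypoxic_fraction, mean_oxygen_percent, total_vegf,
#'   viable_cell_mass, n_vessel_segments, penetration_depth (mm),
#'   full_thickness.
#' @slot snapshots named list of [ContinuumFields-class] snapshots keyed
#'   by time.
#' @slot fields final [ContinuumFields-class].
#' @slot network final [VascularNetwork-class].
#' @slot seed the replicate seed used.
#' @export
setClass("SimulationResult",
  slots = c(
    config = "ScenarioConfig", params = "ModelParameters",
    metrics = "data.frame", snapshots = "list",
    fields = "ContinuumFields", network = "VascularNetwork",
    seed = "integer"
  )
)

setValidity("SimulationResult", function(object) {
  msg <- character(0)
  mt <- object@metrics
  if (nrow(mt)) {
    if (any(diff(mt$time) <= 0)) msg <- c(msg, "metric times must increase")
    fr <- c(mt$anoxic_fraction, mt$hypoxic_fraction)
    if (any(fr < 0 | fr > 1)) msg <- c(msg, "fractions must lie in [0, 1]")
    if (any(mt$anoxic_fraction + mt$hypoxic_fraction > 1 + 1e-12))
      msg <- c(msg, "anoxic + hypoxic fraction must be <= 1")
    halfw <- object@config@dx * min(object@config@grid_nx,
                                    object@config@grid_ny) / 2
    if (any(mt$penetration_depth > halfw + 1e-9))
      msg <- c(msg, "penetration depth exceeds half the domain width")
  }
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic fixture
#'
#' @slot kind one of `"release_curve"`, `"vegf_field"`, `"ec_row"`,
#'   `"bead_layout"`.
#' @slot params kind-specific named list.
#' @slot seed integer seed; fixes the output exactly.
#' @slot noise_sd nonnegative noise level (0 gives the noiseless model).
#' @export
setClass("SyntheticSpec",
  slots = c(kind = "character", params = "list",
            seed = "integer", noise_sd = "numeric"),
  prototype = prototype(kind = "release_curve", params = list(),
                        seed = 1L, noise_sd = 0)
)

setValidity("SyntheticSpec", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("release_curve", "vegf_field", "ec_row",
                          "bead_layout"))
    msg <- c(msg, "unknown synthetic fixture kind")
  if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
  if (length(msg)) msg else TRUE
})
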