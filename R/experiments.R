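#' @include AllClasses.R continuum.R vascular.R bead-release.R
NULL

#' Fraction of implant sites that are anoxic
#'
#' @param oxygen_field nondimensional oxygen matrix.
#' @param p a [ModelParameters-class].
#' @return fraction of sites below the anoxia threshold (0.5\%
#'   dissolved oxygen).
#' @examples
#' anoxicFraction(matrix(percentToNondim(3.7), 5, 5))  # 0
#' @export
anoxicFraction <- function(oxygen_field, p = defaultParameters()) {
  mean(oxygen_field < p@c_anoxia)
}

#' @rdname anoxicFraction
#' @export
hypoxicFraction <- function(oxygen_field, p = defaultParameters()) {
  mean(oxygen_field >= p@c_anoxia & oxygen_field < p@c_hypoxia)
}

#' Vascular penetration depth
#'
#' The deepest point any endothelial agent has reached: the maximum
#' over agents of the minimum lattice distance to a domain edge, in mm.
#' An implant counts as fully vascularized ("full thickness") when the
#' penetration depth reaches 90\% of the half-width.
#'
#' @param network a [VascularNetwork-class].
#' @param cfg a [ScenarioConfig-class] (for `dx` and the grid extent).
#' @return depth in mm (0 for an empty network).
#' @examples
#' penetrationDepth(seedBoundarySprouts(scenarioConfig()),
#'                  scenarioConfig())  # 0: agents sit on the edge
#' @export
penetrationDepth <- function(network, cfg) {
  if (nAgents(network) == 0) return(0)
  s <- network@sites
  d <- pmin(s[, 1] - 1L, cfg@grid_nx - s[, 1],
            s[, 2] - 1L, cfg@grid_ny - s[, 2])
  max(d) * cfg@dx
}

#' @rdname penetrationDepth
#' @export
fullThickness <- function(network, cfg) {
  halfw <- min(cfg@grid_nx, cfg@grid_ny) * cfg@dx / 2
  penetrationDepth(network, cfg) >= 0.9 * halfw
}

.capture_metrics <- function(fields, net, cfg, p) {
  data.frame(
    time = fields@t,
    anoxic_fraction = anoxicFraction(fields@oxygen, p),
    hypoxic_fraction = hypoxicFraction(fields@oxygen, p),
    mean_oxygen_percent = oxygenToPercent(mean(fields@oxygen)),
    total_vegf = sum(fields@vegf) * cfg@dx^2,
    viable_cell_mass = sum(fields@progenitor + fields@fibroblast) * cfg@dx^2,
    n_vessel_segments = nSegments(net),
    penetration_depth = penetrationDepth(net, cfg),
    full_thickness = fullThickness(net, cfg))
}

#' Run one implantation scenario
#'
#' Orchestrates the full hybrid simulation: fields are initialized,
#' beads placed (stochastic, seeded) and boundary sprouts seeded; then
#' every time step applies boundary conditions, advances the continuum
#' fields and the intracellular Dll4-Notch state, and at each growth
#' event reselects tips and lets them advance and anastomose. Implant
#' metrics are captured every `output_interval` days. Runs are fully
#' reproducible: identical configuration and seed give identical
#' results.
#'
#' @param cfg a [ScenarioConfig-class]; must pass [validateConfig()].
#' @param p a [ModelParameters-class].
#' @param keep_snapshots logical; store field snapshots at every
#'   capture time (memory-heavy for long runs).
#' @return a [SimulationResult-class].
#' @examples
#' cfg <- scenarioConfig(grid_nx = 21, grid_ny = 21, t_end = 0.5,
#'                       bead_type = "HOG", bead_fraction = 0.02)
#' res <- runScenario(cfg)
#' finalMetrics(res)$anoxic_fraction
#' @export
runScenario <- function(cfg, p = defaultParameters(),
                        keep_snapshots = FALSE) {
  viol <- validateConfig(cfg, p)
  if (length(viol))
    stop("invalid scenario: ", paste(viol, collapse = "; "))

  fields <- initializeFields(cfg, p)
  beads <- if (cfg@bead_type != "none" && cfg@bead_fraction > 0)
    placeBeads(cfg@grid_nx, cfg@grid_ny, cfg@bead_fraction,
               cfg@bead_type, cfg@seed, p)
  else NULL
  net <- seedBoundarySprouts(cfg, p)
  nb <- .neighborIndex(net)

  n_steps <- round(cfg@t_end / cfg@dt)
  growth_every <- max(1L, round(p@growth_interval / cfg@dt))
  out_every <- max(1L, round(cfg@output_interval / cfg@dt))

  metrics <- vector("list", floor(n_steps / out_every) + 1L)
  snapshots <- list()
  metrics[[1]] <- .capture_metrics(fields, net, cfg, p)
  mi <- 1L
  if (keep_snapshots)
    snapshots[[format(fields@t)]] <- fields

  for (s in seq_len(n_steps)) {
    fields <- applyBoundaryConditions(fields, cfg, p)
    fields <- stepFields(fields, beads, net, cfg, p)
    net <- notchStepNetwork(net, fields@vegf, p, cfg@dt, nb = nb)
    if (s %% growth_every == 0L) {
      net <- selectTips(net, fields@vegf, p)
      net <- growAndAnastomose(net, fields@vegf, cfg, p)
      nb <- .neighborIndex(net)
    }
    if (s %% out_every == 0L) {
      mi <- mi + 1L
      metrics[[mi]] <- .capture_metrics(fields, net, cfg, p)
      if (keep_snapshots)
        snapshots[[format(fields@t)]] <- fields
    }
  }

  new("SimulationResult",
      config = cfg, params = p,
      metrics = do.call(rbind, metrics[seq_len(mi)]),
      snapshots = snapshots, fields = fields, network = net,
      seed = cfg@seed)
}

#' Sweep the bead conditions of the implantation study
#'
#' Runs the bead-free control plus CPO and HOG at the given area
#' fractions (1\%, 2\% and 4\% by default), `n_replicates` seeds each,
#' and aggregates the final metrics per condition (median and
#' interquartile spread). A consistency check flags any metric whose
#' replicate coefficient of variation exceeds `cv_bound`.
#'
#' @param base_cfg the [ScenarioConfig-class] shared by all conditions;
#'   its `bead_type`/`bead_fraction` are overridden, and replicate `k`
#'   uses seed `base_cfg@seed + k - 1`.
#' @param p a [ModelParameters-class].
#' @param fractions bead area fractions to sweep.
#' @param n_replicates replicate count (default from `base_cfg`).
#' @param cv_bound coefficient-of-variation bound for the consistency
#'   flag.
#' @return list with `summary` (one row per condition and metric:
#'   median, q25, q75, cv, consistent) and `replicates` (final metrics
#'   of every run).
#' @export
runConditionSweep <- function(base_cfg, p = defaultParameters(),
                              fractions = c(0.01, 0.02, 0.04),
                              n_replicates = base_cfg@n_replicates,
                              cv_bound = 0.5) {
  conds <- rbind(
    data.frame(bead_type = "none", bead_fraction = 0),
    expand.grid(bead_type = c("CPO", "HOG"), bead_fraction = fractions,
                stringsAsFactors = FALSE))
  reps <- list()
  for (i in seq_len(nrow(conds))) {
    for (k in seq_len(n_replicates)) {
      cfg <- base_cfg
      cfg@bead_type <- conds$bead_type[i]
      cfg@bead_fraction <- conds$bead_fraction[i]
      cfg@seed <- base_cfg@seed + k - 1L
      fin <- finalMetrics(runScenario(cfg, p))
      fin$bead_type <- cfg@bead_type
      fin$bead_fraction <- cfg@bead_fraction
      fin$seed <- cfg@seed
      reps[[length(reps) + 1L]] <- fin
    }
  }
  reps <- do.call(rbind, reps)

  met_cols <- c("anoxic_fraction", "hypoxic_fraction",
                "mean_oxygen_percent", "total_vegf", "viable_cell_mass",
                "n_vessel_segments", "penetration_depth")
  rows <- list()
  for (i in seq_len(nrow(conds))) {
    sel <- reps$bead_type == conds$bead_type[i] &
      reps$bead_fraction == conds$bead_fraction[i]
    for (mc in met_cols) {
      v <- reps[sel, mc]
      mu <- mean(v)
      cv <- if (n_replicates > 1 && mu != 0) stats::sd(v) / abs(mu) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        bead_type = conds$bead_type[i],
        bead_fraction = conds$bead_fraction[i],
        metric = mc,
        median = stats::median(v),
        q25 = unname(stats::quantile(v, 0.25)),
        q75 = unname(stats::quantile(v, 0.75)),
        cv = cv,
        consistent = n_replicates == 1 || cv <= cv_bound)
    }
  }
  list(summary = do.call(rbind, rows), replicates = reps)
}
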