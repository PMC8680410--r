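#' @include AllClasses.R
NULL

#' Default model parameters
#'
#' Returns the default [ModelParameters-class]. The printed constants of
#' the release law are `G_n = 2.2`, `H_n = 0.11`, `tau = 0.5` per day
#' for CPO and `0.05` per day for HOGs; the fibroblast VEGF production
#' multiplier is 10; the implant initializes at 3.7\% oxygen tension
#' with matrix and progenitor densities of 0.1, and cells enter over the
#' boundary at a Dirichlet density of 0.01 for the first 3 days. Oxygen
#' is nondimensionalized so that 1.0 is 21\% dissolved oxygen
#' (atmospheric normoxia); under that convention `H_n = 0.11`
#' corresponds to about 2.3\% oxygen, inside the hypoxic band, so bead
#' release self-limits exactly where hypoxic stimulation is wanted.
#' Constants of the tissue and intracellular kinetics carry documented
#' package defaults (see the methods vignette for the calibration
#' rationale).
#'
#' @return a validated [ModelParameters-class] object.
#' @examples
#' p <- defaultParameters()
#' p@G_n                      # 2.2
#' oxygenToPercent(p@c_init)  # 3.7
#' @export
defaultParameters <- function() {
  new("ModelParameters")
}

#' Convert nondimensional oxygen to percent dissolved oxygen
#'
#' The simulator's oxygen convention is fraction-of-normoxia: 1.0 is
#' 21\% dissolved oxygen.
#'
#' @param c nondimensional oxygen (vectorized), `c >= 0`.
#' @return percent dissolved oxygen, `21 * c`.
#' @examples
#' oxygenToPercent(1)          # 21
#' oxygenToPercent(0.5 / 21)   # the anoxia threshold, 0.5
#' @export
oxygenToPercent <- function(c) {
  if (any(c < 0)) stop("nondimensional oxygen must be >= 0")
  21 * c
}

#' @rdname oxygenToPercent
#' @param percent percent dissolved oxygen, `>= 0`.
#' @export
percentToNondim <- function(percent) {
  if (any(percent < 0)) stop("percent oxygen must be >= 0")
  percent / 21
}

#' Construct a scenario configuration
#'
#' @param grid_nx,grid_ny lattice site counts.
#' @param dx lattice spacing (mm).
#' @param t_end duration (days).
#' @param dt time step (days).
#' @param bead_type `"none"`, `"CPO"` or `"HOG"`.
#' @param bead_fraction fraction of sites occupied by beads, between 0
#'   and 0.1.
#' @param seed integer seed for bead placement.
#' @param n_replicates replicate count used by [runConditionSweep()].
#' @param output_interval days between metric captures.
#' @return a [ScenarioConfig-class].
#' @examples
#' cfg <- scenarioConfig(bead_type = "HOG", bead_fraction = 0.02)
#' validateConfig(cfg, defaultParameters())  # character(0)
#' @export
scenarioConfig <- function(grid_nx = 100L, grid_ny = 100L, dx = 0.04,
                           t_end = 7, dt = 0.002,
                           bead_type = c("none", "CPO", "HOG"),
                           bead_fraction = 0, seed = 1L,
                           n_replicates = 5L, output_interval = 0.25) {
  bead_type <- match.arg(bead_type)
  new("ScenarioConfig",
      grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
      dx = dx, t_end = t_end, dt = dt,
      bead_type = bead_type, bead_fraction = bead_fraction,
      seed = as.integer(seed), n_replicates = as.integer(n_replicates),
      output_interval = output_interval)
}

#' Validate a scenario against the model parameters
#'
#' Checks every configuration invariant and the explicit-diffusion
#' stability bound `dt <= dx^2 / (4 max(D_oxygen, D_vegf, D_cell))`.
#' Violations are returned as data, not thrown.
#'
#' @param cfg a [ScenarioConfig-class].
#' @param p a [ModelParameters-class].
#' @return character vector of violation messages; empty if valid.
#' @examples
#' length(validateConfig(scenarioConfig(), defaultParameters()))  # 0
#' @export
validateConfig <- function(cfg, p = defaultParameters()) {
  out <- character(0)
  v <- validObject(cfg, test = TRUE)
  if (is.character(v)) out <- c(out, v)
  v <- validObject(p, test = TRUE)
  if (is.character(v)) out <- c(out, v)
  if (cfg@bead_fraction < 0)
    out <- c(out, "bead_fraction must be nonnegative")
  if (cfg@bead_type != "none" &&
      round(cfg@bead_fraction * cfg@grid_nx * cfg@grid_ny) < 1)
    out <- c(out, "bead_fraction places no beads on this grid")
  dmax <- max(p@D_oxygen, p@D_vegf, p@D_cell)
  if (dmax > 0) {
    bound <- cfg@dx^2 / (4 * dmax)
    if (cfg@dt > bound)
      out <- c(out, sprintf(
        "dt = %g exceeds the diffusion stability bound dx^2/(4 Dmax) = %g",
        cfg@dt, bound))
  }
  if (cfg@output_interval < cfg@dt)
    out <- c(out, "output_interval must be at least dt")
  if (p@growth_interval < cfg@dt)
    out <- c(out, "growth_interval must be at least dt")
  out
}

#' Read a scenario configuration from a key/value text file
#'
#' The file holds one `key = value` pair per line; `#` starts a comment.
#' Keys are the [scenarioConfig()] argument names; unknown keys are an
#' error, missing keys keep their defaults.
#'
#' @param path path to the configuration file.
#' @return a [ScenarioConfig-class].
#' @seealso [writeScenarioConfig()]
#' @export
readScenarioConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("malformed configuration line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(formals(scenarioConfig)))
      stop("unknown configuration key: ", key)
    args[[key]] <- if (key == "bead_type") val else as.numeric(val)
  }
  do.call(scenarioConfig, args)
}

#' Write a scenario configuration as a key/value text file
#'
#' @param cfg a [ScenarioConfig-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScenarioConfig <- function(cfg, path) {
  keys <- c("grid_nx", "grid_ny", "dx", "t_end", "dt", "bead_type",
            "bead_fraction", "seed", "n_replicates", "output_interval")
  vals <- vapply(keys, function(k) format(slot(cfg, k), digits = 15),
                 character(1))
  writeLines(paste(keys, "=", vals), path)
  invisible(path)
}
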