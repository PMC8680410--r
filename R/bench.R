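#' @include AllClasses.R
NULL

#' Bench-assay calculators
#'
#' Closed-form formulas used when characterizing the oxygen-generating
#' micromaterials and the GelMA hydrogel bulk: CPO encapsulation
#' efficiency and loading capacity of the microparticles, degree of
#' methacrylation of the gelatin (OPA fluorescence assay), and the
#' hydrogel swelling ratio. Values outside the physically expected
#' range are returned as-is with a warning rather than clamped, so
#' measurement anomalies surface instead of vanishing. Each formula is
#' invariant under uniform rescaling of its mass or intensity inputs.
#'
#' @name benchCalcs
NULL

#' @describeIn benchCalcs percent of the CPO charge retained after
#'   washing: `100 (total - lost) / total`.
#' @param total total CPO mass added (mg), `> 0`.
#' @param lost CPO mass lost in washing (mg).
#' @export
encapsulationEfficiency <- function(total, lost) {
  if (any(total <= 0)) stop("total CPO mass must be positive")
  out <- 100 * (total - lost) / total
  if (any(out < 0 | out > 100))
    warning("encapsulation efficiency outside [0, 100]%; check inputs")
  out
}

#' @describeIn benchCalcs percent of the final microparticle mass that
#'   is encapsulated CPO: `100 encapsulated / final_mass`.
#' @param encapsulated encapsulated CPO mass (mg).
#' @param final_mass final microparticle mass (mg), `> 0`.
#' @export
loadingCapacity <- function(encapsulated, final_mass) {
  if (any(final_mass <= 0)) stop("final microparticle mass must be positive")
  out <- 100 * encapsulated / final_mass
  if (any(out < 0 | out > 100))
    warning("loading capacity outside [0, 100]%; check inputs")
  out
}

#' @describeIn benchCalcs degree of methacrylation from OPA
#'   fluorescence: `1 - (Is - Ib) / (Istd - Ib)`.
#' @param Is sample fluorescence intensity.
#' @param Ib blank intensity.
#' @param Istd unmodified-gelatin standard intensity; must differ from
#'   `Ib`.
#' @export
degreeOfMethacrylation <- function(Is, Ib, Istd) {
  if (any(Istd == Ib))
    stop("standard and blank intensities must differ")
  out <- 1 - (Is - Ib) / (Istd - Ib)
  if (any(out < 0 | out > 1))
    warning("degree of methacrylation outside [0, 1]; check inputs")
  out
}

#' @describeIn benchCalcs percent mass gain on swelling:
#'   `100 (Wt - W0) / W0`.
#' @param W0 initial hydrogel weight (mg), `> 0`.
#' @param Wt swollen weight (mg).
#' @export
swellingRatio <- function(W0, Wt) {
  if (any(W0 <= 0)) stop("initial weight must be positive")
  100 * (Wt - W0) / W0
}
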