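#' @include AllClasses.R
NULL

#' Accessors for simulator objects
#'
#' Small accessor generics so that downstream code never reaches into
#' slots directly.
#'
#' @param object an oxybeads S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("beadSites", function(object) standardGeneric("beadSites"))
#' @rdname accessors
#' @export
setGeneric("beadType", function(object) standardGeneric("beadType"))
#' @rdname accessors
#' @export
setGeneric("nBeads", function(object) standardGeneric("nBeads"))
#' @rdname accessors
#' @export
setGeneric("oxygenField", function(object) standardGeneric("oxygenField"))
#' @rdname accessors
#' @export
setGeneric("vegfField", function(object) standardGeneric("vegfField"))
#' @rdname accessors
#' @export
setGeneric("progenitorField", function(object) standardGeneric("progenitorField"))
#' @rdname accessors
#' @export
setGeneric("fibroblastField", function(object) standardGeneric("fibroblastField"))
#' @rdname accessors
#' @export
setGeneric("matrixField", function(object) standardGeneric("matrixField"))
#' @rdname accessors
#' @export
setGeneric("simTime", function(object) standardGeneric("simTime"))
#' @rdname accessors
#' @export
setGeneric("agentSites", function(object) standardGeneric("agentSites"))
#' @rdname accessors
#' @export
setGeneric("agentRoles", function(object) standardGeneric("agentRoles"))
#' @rdname accessors
#' @export
setGeneric("agentState", function(object) standardGeneric("agentState"))
#' @rdname accessors
#' @export
setGeneric("nAgents", function(object) standardGeneric("nAgents"))
#' @rdname accessors
#' @export
setGeneric("segments", function(object) standardGeneric("segments"))
#' @rdname accessors
#' @export
setGeneric("nSegments", function(object) standardGeneric("nSegments"))
#' @rdname accessors
#' @export
setGeneric("perfusedSegments", function(object) standardGeneric("perfusedSegments"))
#' @rdname accessors
#' @export
setGeneric("boundaryRoots", function(object) standardGeneric("boundaryRoots"))
#' @rdname accessors
#' @export
setGeneric("tipCount", function(object) standardGeneric("tipCount"))
#' @rdname accessors
#' @export
setGeneric("metricsTable", function(object) standardGeneric("metricsTable"))
#' @rdname accessors
#' @export
setGeneric("finalMetrics", function(object) standardGeneric("finalMetrics"))
#' @rdname accessors
#' @export
setGeneric("scenario", function(object) standardGeneric("scenario"))
#' @rdname accessors
#' @export
setGeneric("releaseTimes", function(object) standardGeneric("releaseTimes"))
#' @rdname accessors
#' @export
setGeneric("releaseRates", function(object) standardGeneric("releaseRates"))

#' Generate a synthetic fixture from a specification
#'
#' Dispatches on the `kind` of a [SyntheticSpec-class] to the concrete
#' generators [makeReleaseCurve()], [makeVegfGradient()], [makeEcRow()]
#' and [placeBeads()].
#'
#' @param spec a [SyntheticSpec-class].
#' @return the generated fixture.
#' @export
setGeneric("generateSynthetic", function(spec) standardGeneric("generateSynthetic"))

## ---- accessor methods -----------------------------------------------------

#' @rdname accessors
setMethod("beadSites", "BeadSet", function(object) object@sites)
#' @rdname accessors
setMethod("beadType", "BeadSet", function(object) object@bead_type)
#' @rdname accessors
setMethod("nBeads", "BeadSet", function(object) nrow(object@sites))

#' @rdname accessors
setMethod("oxygenField", "ContinuumFields", function(object) object@oxygen)
#' @rdname accessors
setMethod("vegfField", "ContinuumFields", function(object) object@vegf)
#' @rdname accessors
setMethod("progenitorField", "ContinuumFields", function(object) object@progenitor)
#' @rdname accessors
setMethod("fibroblastField", "ContinuumFields", function(object) object@fibroblast)
#' @rdname accessors
setMethod("matrixField", "ContinuumFields", function(object) object@fibrous)
#' @rdname accessors
setMethod("simTime", "ContinuumFields", function(object) object@t)

#' @rdname accessors
setMethod("agentSites", "VascularNetwork", function(object) object@sites)
#' @rdname accessors
setMethod("agentRoles", "VascularNetwork", function(object) object@role)
#' @rdname accessors
setMethod("agentState", "VascularNetwork", function(object) object@state)
#' @rdname accessors
setMethod("nAgents", "VascularNetwork", function(object) nrow(object@sites))
#' @rdname accessors
setMethod("segments", "VascularNetwork", function(object) object@segments)
#' @rdname accessors
setMethod("nSegments", "VascularNetwork", function(object) nrow(object@segments))
#' @rdname accessors
setMethod("perfusedSegments", "VascularNetwork", function(object) object@perfused)
#' @rdname accessors
setMethod("boundaryRoots", "VascularNetwork", function(object) object@boundary_roots)
#' @rdname accessors
setMethod("tipCount", "VascularNetwork", function(object) sum(object@role == "tip"))

#' @rdname accessors
setMethod("metricsTable", "SimulationResult", function(object) object@metrics)
#' @rdname accessors
setMethod("finalMetrics", "SimulationResult",
          function(object) object@metrics[nrow(object@metrics), , drop = FALSE])
#' @rdname accessors
setMethod("scenario", "SimulationResult", function(object) object@config)
#' @rdname accessors
setMethod("oxygenField", "SimulationResult", function(object) object@fields@oxygen)
#' @rdname accessors
setMethod("vegfField", "SimulationResult", function(object) object@fields@vegf)

#' @rdname accessors
setMethod("releaseTimes", "ReleaseCurve", function(object) object@times)
#' @rdname accessors
setMethod("releaseRates", "ReleaseCurve", function(object) object@rates)

## ---- show methods ---------------------------------------------------------

setMethod("show", "ModelParameters", function(object) {
  cat("ModelParameters\n")
  cat(sprintf("  release: G_n = %g, H_n = %g (Hill h = %g), tau CPO/HOG = %g/%g per day\n",
              object@G_n, object@H_n, object@hill_h, object@tau_cpo, object@tau_hog))
  cat(sprintf("  oxygen: init %.2f%%, anoxia < %.2f%%, hypoxia < %.2f%% (1.0 = 21%%)\n",
              21 * object@c_init, 21 * object@c_anoxia, 21 * object@c_hypoxia))
  cat(sprintf("  transport: D(oxygen, VEGF, cell) = %g, %g, %g mm^2/day\n",
              object@D_oxygen, object@D_vegf, object@D_cell))
  cat(sprintf("  tip selection: theta_tip = %g, growth every %g day\n",
              object@theta_tip, object@growth_interval))
})

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf("ScenarioConfig: %d x %d sites (dx = %g mm), %g days (dt = %g)\n",
              object@grid_nx, object@grid_ny, object@dx, object@t_end, object@dt))
  cat(sprintf("  beads: %s at %.1f%% of sites; seed %d; output every %g day\n",
              object@bead_type, 100 * object@bead_fraction, object@seed,
              object@output_interval))
})

setMethod("show", "BeadSet", function(object) {
  cat(sprintf("BeadSet: %d %s beads on %d x %d lattice (seed %d)\n",
              nrow(object@sites), object@bead_type,
              object@grid_nx, object@grid_ny, object@placement_seed))
  cat(sprintf("  release: G_n = %g, H_n = %g, h = %g, tau = %g per day\n",
              object@G_n, object@H_n, object@hill_h, object@tau))
})

setMethod("show", "ReleaseCurve", function(object) {
  cat(sprintf("ReleaseCurve: %d points over %g-%g days (noise sd %g)\n",
              length(object@times), min(object@times), max(object@times),
              object@noise_sd))
})

setMethod("show", "ContinuumFields", function(object) {
  cat(sprintf("ContinuumFields at t = %.3f days (%d x %d)\n",
              object@t, nrow(object@oxygen), ncol(object@oxygen)))
  cat(sprintf("  mean oxygen %.2f%%, total VEGF %.3f, mean cells %.3f\n",
              21 * mean(object@oxygen), sum(object@vegf),
              mean(object@progenitor + object@fibroblast)))
})

setMethod("show", "VascularNetwork", function(object) {
  cat(sprintf("VascularNetwork: %d agents (%d tips), %d segments (%d perfused)\n",
              nrow(object@sites), sum(object@role == "tip"),
              nrow(object@segments), sum(object@perfused)))
})

setMethod("show", "SimulationResult", function(object) {
  cat("SimulationResult\n")
  show(object@config)
  if (nrow(object@metrics)) {
    fin <- object@metrics[nrow(object@metrics), ]
    cat(sprintf("  day %.1f: anoxic %.3f, mean O2 %.2f%%, VEGF %.1f, depth %.2f mm%s\n",
                fin$time, fin$anoxic_fraction, fin$mean_oxygen_percent,
                fin$total_vegf, fin$penetration_depth,
                if (isTRUE(fin$full_thickness)) " (full thickness)" else ""))
  }
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: kind = %s, seed = %d, noise_sd = %g\n",
              object@kind, object@seed, object@noise_sd))
})
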