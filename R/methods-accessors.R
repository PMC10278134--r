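#' @include AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("frequencies", "NormalModeSet", function(object, ...) object@frequencies)

#' @rdname accessors
#' @export
setMethod("frequencies", "VibronicCoupling", function(object, ...) object@frequencies)

#' @rdname accessors
#' @export
setMethod("modeVectors", "NormalModeSet", function(object, ...) object@modes)

#' @rdname accessors
#' @export
setMethod("atomMasses", "NormalModeSet", function(object, ...) object@masses)

#' @rdname accessors
#' @export
setMethod("hrFactors", "VibronicCoupling", function(object, ...) object@hrFactors)

#' @rdname accessors
#' @export
setMethod("reorgEnergies", "VibronicCoupling",
          function(object, ...) object@reorgEnergies)

#' @rdname accessors
#' @export
setMethod("totalReorg", "VibronicCoupling",
          function(object, ...) sum(object@reorgEnergies))

#' @rdname accessors
#' @export
setMethod("energyGrid", "Spectrum", function(object, ...) object@energy)

#' @rdname accessors
#' @export
setMethod("intensities", "Spectrum", function(object, ...) object@intensity)

#' @rdname accessors
#' @export
setMethod("isNormalized", "Spectrum", function(object, ...) object@normalized)

#' @rdname accessors
#' @export
setMethod("excitationEnergies", "FrameEnsemble",
          function(object, ...) object@energies)

#' @rdname accessors
#' @export
setMethod("oscStrengths", "FrameEnsemble", function(object, ...) object@oscStrengths)

#' @rdname accessors
#' @export
setMethod("frameState", "FrameEnsemble", function(object, ...) object@state)

#' @rdname accessors
#' @export
setMethod("frameReplica", "FrameEnsemble", function(object, ...) object@replica)

#' @rdname accessors
#' @export
setMethod("nFrames", "FrameEnsemble", function(object, ...) nrow(object@energies))

#' @rdname accessors
#' @export
setMethod("nFrames", "TrajectoryView", function(object, ...) dim(object@coords)[3])

#' @rdname accessors
#' @export
setMethod("nAtoms", "TrajectoryView", function(object, ...) dim(object@coords)[1])

#' @rdname accessors
#' @export
setMethod("coords", "TrajectoryView", function(object, ...) object@coords)

#' @rdname accessors
#' @export
setMethod("ciBounds", "IntervalEstimate",
          function(object, ...) c(lower = object@lower, upper = object@upper))

setMethod("show", "NormalModeSet", function(object) {
  nm <- length(object@frequencies)
  cat("NormalModeSet:", nm, "modes over", length(object@masses), "atoms\n")
  cat("  projected rigid modes:", object@nProjected,
      "| imaginary:", sum(object@imaginary), "\n")
  if (nm)
    cat("  wavenumber range:",
        sprintf("%.1f - %.1f cm^-1", min(object@frequencies),
                max(object@frequencies)), "\n")
  invisible(NULL)
})

setMethod("show", "VibronicCoupling", function(object) {
  cat("VibronicCoupling:", length(object@hrFactors), "modes,",
      object@nExcluded, "excluded below cutoff\n")
  cat(sprintf("  total reorganization energy: %.4f eV\n",
              sum(object@reorgEnergies)))
  invisible(NULL)
})

setMethod("show", "SpectralDensity", function(object) {
  cat("SpectralDensity:", length(object@stickFreqs), "sticks,",
      object@kind, "broadening, width", object@width, "cm^-1\n")
  invisible(NULL)
})

setMethod("show", "Lineshape", function(object) {
  cat("Lineshape g(t):", length(object@time), "time points, t_max",
      sprintf("%.0f fs,", max(object@time)), "T =", object@temperature, "K\n")
  invisible(NULL)
})

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum (", object@provenance, "): ",
      length(object@energy), " points on [",
      sprintf("%.3f, %.3f", min(object@energy), max(object@energy)),
      "] eV", if (object@normalized) ", unit area" else "", "\n", sep = "")
  invisible(NULL)
})

setMethod("show", "FrameEnsemble", function(object) {
  cat("FrameEnsemble:", nrow(object@energies), "frames x",
      ncol(object@energies), "states\n")
  print(table(object@state))
  invisible(NULL)
})

setMethod("show", "TrajectoryView", function(object) {
  cat("TrajectoryView:", dim(object@coords)[1], "atoms,",
      dim(object@coords)[3], "frames,",
      length(unique(object@resNos)), "residues\n")
  invisible(NULL)
})

setMethod("show", "IntervalEstimate", function(object) {
  cat(sprintf("mean %.4g, 95%% CI [%.4g, %.4g] (n_boot = %d, seed = %d)\n",
              object@mean, object@lower, object@upper, object@nBoot,
              object@seed))
  invisible(NULL)
})
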