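#' @include AllClasses.R vibronic.R
NULL

#' Select the two bright states per MD frame
#'
#' Ensembles sampled along an MD trajectory scatter the oscillator strength of
#' the second bright band over different adiabatic states (typically S3 or S4)
#' from frame to frame. Per frame, S1 is the lowest state, and S2' is defined
#' as the state of largest oscillator strength among states of index >= 2.
#' Ties (within `tieTol`) are resolved towards the lower-energy state with a
#' warning.
#'
#' @param ensemble a [FrameEnsemble-class] (>= 3 states per frame).
#' @param tieTol oscillator-strength tie tolerance.
#' @return the ensemble with `s1Index`/`s2pIndex` filled per frame.
#' @export
selectBrightStates <- function(ensemble, tieTol = 1e-6) {
  stopifnot(is(ensemble, "FrameEnsemble"))
  ns <- ncol(ensemble@energies)
  if (ns < 3L) stopf("need at least 3 states per frame")
  nf <- nrow(ensemble@energies)
  s2p <- integer(nf)
  tie <- FALSE
  for (r in seq_len(nf)) {
    f <- ensemble@oscStrengths[r, ]
    cand <- 2:ns
    best <- max(f[cand])
    top <- cand[f[cand] >= best - tieTol]
    if (length(top) > 1L) {
      tie <- TRUE
      top <- top[which.min(ensemble@energies[r, top])]
    }
    s2p[r] <- top[1]
  }
  if (tie) warning("oscillator-strength tie; lower-energy state chosen")
  ensemble@s1Index <- rep(1L, nf)
  ensemble@s2pIndex <- s2p
  validObject(ensemble)
  ensemble
}

#' Per-frame band energies of a selected bright state
#'
#' @param ensemble a [FrameEnsemble-class] after [selectBrightStates()].
#' @param band "S1" or "S2p".
#' @param state optional filter, "dark" or "light".
#' @return numeric vector of vertical excitation energies (eV), one per frame.
#' @export
bandEnergies <- function(ensemble, band = c("S1", "S2p"), state = NULL) {
  stopifnot(is(ensemble, "FrameEnsemble"))
  band <- match.arg(band)
  idx <- if (band == "S1") ensemble@s1Index else ensemble@s2pIndex
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stopf("band energies missing for frames: %s",
          paste(utils::head(bad, 10L), collapse = ", "))
  }
  en <- ensemble@energies[cbind(seq_len(nrow(ensemble@energies)), idx)]
  if (!is.null(state)) en <- en[ensemble@state == state]
  en
}

#' Inhomogeneously broadened spectrum from an MD energy ensemble
#'
#' Convolves a (normalized) homogeneous lineshape with the inhomogeneous
#' distribution of vertical excitation energies: each frame contributes the
#' homogeneous spectrum re-centred at that frame's excitation energy, with
#' equal weight by default,
#' sigma_inh(E) = (1/N) sum_f sigma_hom(E - (dE_f - E_vert)).
#' The trapezoidal area is preserved; the first moment of the result equals
#' the ensemble mean energy plus the homogeneous spectrum's moment offset from
#' its own `eVert`.
#'
#' @param hom a normalized homogeneous [Spectrum-class].
#' @param energies per-frame band energies (eV), or a [FrameEnsemble-class]
#'   (then `band`/`state` pick the energies via [bandEnergies()]).
#' @param eVert the vertical energy the homogeneous spectrum was built at.
#' @param band,state forwarded to [bandEnergies()] when `energies` is a
#'   [FrameEnsemble-class].
#' @param weights optional per-frame weights (e.g. oscillator strengths);
#'   default equal weights.
#' @return a [Spectrum-class] with provenance "inhomogeneous" on the same
#'   energy grid.
#' @export
inhomogeneousSpectrum <- function(hom, energies, eVert, band = "S1",
                                  state = NULL, weights = NULL) {
  stopifnot(is(hom, "Spectrum"))
  if (is(energies, "FrameEnsemble"))
    energies <- bandEnergies(energies, band, state)
  if (!hom@normalized) stopf("homogeneous spectrum must be normalized")
  if (length(energies) == 0L) stopf("empty ensemble")
  if (any(!is.finite(energies)))
    stopf("band energies missing/non-finite for frames: %s",
          paste(utils::head(which(!is.finite(energies)), 10L), collapse = ", "))
  if (is.null(weights)) weights <- rep(1, length(energies))
  weights <- weights / sum(weights)
  grid <- hom@energy
  acc <- numeric(length(grid))
  for (i in seq_along(energies)) {
    shift <- energies[i] - eVert
    acc <- acc + weights[i] *
      stats::approx(grid + shift, hom@intensity, xout = grid,
                    yleft = 0, yright = 0)$y
  }
  new("Spectrum", energy = grid, intensity = pmax(acc, 0),
      normalized = FALSE, provenance = "inhomogeneous")
}

#' Locate the first maximum of a spectrum
#'
#' The lowest-energy local maximum whose intensity exceeds `frac` of the
#' global maximum (operational definition of a band's "first maximum").
#'
#' @param spec a [Spectrum-class].
#' @param frac threshold fraction of the global maximum.
#' @return list with `energy` (eV) and `intensity`.
#' @export
firstMaximum <- function(spec, frac = 0.05) {
  stopifnot(is(spec, "Spectrum"))
  y <- spec@intensity
  n <- length(y)
  thr <- frac * max(y)
  isMax <- c(FALSE, y[2:(n - 1)] >= y[1:(n - 2)] &
                    y[2:(n - 1)] > y[3:n], FALSE) & y > thr
  idx <- which(isMax)
  if (!length(idx)) stopf("no local maximum found above %g of global max", frac)
  i <- idx[1]
  list(energy = spec@energy[i], intensity = y[i])
}

#' Align spectra to a reference by a common shift and scale
#'
#' Determines one energy shift and one intensity scale that bring the first
#' maximum of the designated spectrum (`spectra[[which]]`) onto the first
#' maximum of `reference`, then applies the same affine map to every spectrum
#' in the list. Differences of peak positions between spectra are invariant
#' under this common transform.
#'
#' @param spectra list of [Spectrum-class] objects.
#' @param reference a [Spectrum-class] with an identifiable first maximum.
#' @param which index of the spectrum used to determine the shift/scale.
#' @param frac threshold for [firstMaximum()].
#' @return list with `spectra` (aligned, provenance "aligned"), `shift` (eV)
#'   and `scale`.
#' @export
alignSpectra <- function(spectra, reference, which = 1L, frac = 0.05) {
  stopifnot(is(reference, "Spectrum"))
  if (!length(spectra)) stopf("no spectra to align")
  refMax <- firstMaximum(reference, frac)
  desMax <- firstMaximum(spectra[[which]], frac)
  shift <- refMax$energy - desMax$energy
  scale <- refMax$intensity / desMax$intensity
  aligned <- lapply(spectra, function(s) {
    new("Spectrum", energy = s@energy + shift,
        intensity = s@intensity * scale,
        normalized = FALSE, provenance = "aligned")
  })
  list(spectra = aligned, shift = shift, scale = scale)
}
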