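#' @import methods
NULL

#' Mass-weighted normal modes of a molecular Hessian
#'
#' Holds harmonic vibrational frequencies (cm^-1), the mass-weighted Cartesian
#' displacement vectors (one column per retained mode, unit norm), the atomic
#' masses (amu) and bookkeeping about projected-out rigid-body modes.
#' A negative entry in `frequencies` denotes an imaginary frequency (the
#' magnitude is reported; `imaginary` flags it).
#'
#' @slot frequencies numeric, harmonic wavenumbers in cm^-1 (signed; negative
#'   means imaginary).
#' @slot modes matrix, 3N x n_modes mass-weighted displacement vectors,
#'   orthonormal columns.
#' @slot masses numeric, per-atom masses in amu.
#' @slot nProjected integer, number of rigid translation/rotation modes removed.
#' @slot imaginary logical, per retained mode.
#' @slot lowFreqCutoff numeric, wavenumber below which modes are dropped from
#'   downstream vibronic couplings (cm^-1).
#' @exportClass NormalModeSet
setClass("NormalModeSet",
  representation(
    frequencies   = "numeric",
    modes         = "matrix",
    masses        = "numeric",
    nProjected    = "integer",
    imaginary     = "logical",
    lowFreqCutoff = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    nm <- ncol(object@modes)
    if (length(object@frequencies) != nm)
      msg <- c(msg, "length(frequencies) must equal ncol(modes)")
    if (length(object@imaginary) != nm)
      msg <- c(msg, "length(imaginary) must equal ncol(modes)")
    if (nrow(object@modes) != 3L * length(object@masses))
      msg <- c(msg, "modes must have 3 * n_atoms rows")
    if (nm > 0) {
      gram <- crossprod(object@modes)
      if (max(abs(gram - diag(nm))) > 1e-8)
        msg <- c(msg, "mode vectors must be orthonormal to 1e-8")
    }
    if (!(object@nProjected %in% 5:6))
      msg <- c(msg, "nProjected must be 5 or 6")
    if (length(msg)) msg else TRUE
  }
)

#' Per-mode vibronic couplings from the vertical-gradient model
#'
#' Huang-Rhys factors S_j and reorganization energies lambda_j = S_j * hbar
#' omega_j for each retained normal mode; the total reorganization energy is
#' their sum.
#'
#' @slot frequencies numeric, mode wavenumbers in cm^-1.
#' @slot hrFactors numeric, dimensionless Huang-Rhys factors, >= 0.
#' @slot reorgEnergies numeric, per-mode reorganization energies in eV.
#' @slot nExcluded integer, modes dropped below the low-frequency cutoff.
#' @exportClass VibronicCoupling
setClass("VibronicCoupling",
  representation(
    frequencies   = "numeric",
    hrFactors     = "numeric",
    reorgEnergies = "numeric",
    nExcluded     = "integer"
  ),
  validity = function(object) {
    msg <- character()
    n <- length(object@frequencies)
    if (length(object@hrFactors) != n || length(object@reorgEnergies) != n)
      msg <- c(msg, "frequencies, hrFactors and reorgEnergies must align")
    if (any(object@hrFactors < 0))
      msg <- c(msg, "Huang-Rhys factors must be non-negative")
    if (length(msg)) msg else TRUE
  }
)

#' Broadened spectral density with its discrete sticks
#'
#' J(omega) = pi * sum_j S_j omega_j^2 B(omega - omega_j) on a wavenumber grid,
#' with B a unit-area Lorentzian or Gaussian kernel. The discrete sticks
#' (omega_j, S_j) are retained so that downstream lineshape integrals can be
#' evaluated exactly.
#'
#' @slot omega numeric, wavenumber grid (cm^-1).
#' @slot values numeric, J(omega) on the grid (cm^-1 units, >= 0).
#' @slot stickFreqs numeric, mode wavenumbers (cm^-1).
#' @slot stickS numeric, Huang-Rhys factors.
#' @slot kind character, "lorentzian" or "gaussian".
#' @slot width numeric, kernel width (cm^-1).
#' @exportClass SpectralDensity
setClass("SpectralDensity",
  representation(
    omega      = "numeric",
    values     = "numeric",
    stickFreqs = "numeric",
    stickS     = "numeric",
    kind       = "character",
    width      = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@omega) != length(object@values))
      msg <- c(msg, "omega and values must align")
    if (any(object@values < -1e-12))
      msg <- c(msg, "spectral density must be non-negative")
    if (!object@kind %in% c("lorentzian", "gaussian"))
      msg <- c(msg, "kind must be 'lorentzian' or 'gaussian'")
    if (object@width <= 0)
      msg <- c(msg, "width must be positive")
    if (length(msg)) msg else TRUE
  }
)

#' Second-order cumulant lineshape function g(t)
#'
#' @slot time numeric, uniform time grid in fs.
#' @slot g complex, lineshape function on the grid; g(0) = 0.
#' @slot temperature numeric, kelvin.
#' @exportClass Lineshape
setClass("Lineshape",
  representation(
    time        = "numeric",
    g           = "complex",
    temperature = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@time) != length(object@g))
      msg <- c(msg, "time and g must align")
    if (length(object@g) && Mod(object@g[1]) > 1e-12)
      msg <- c(msg, "g(0) must vanish")
    if (object@temperature < 0)
      msg <- c(msg, "temperature must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Absorption spectrum on an energy grid
#'
#' @slot energy numeric, energy grid in eV (increasing).
#' @slot intensity numeric, non-negative intensities (arbitrary units unless
#'   normalized).
#' @slot normalized logical, TRUE when the trapezoidal area is 1.
#' @slot provenance character, one of "homogeneous", "inhomogeneous", "aligned".
#' @exportClass Spectrum
setClass("Spectrum",
  representation(
    energy     = "numeric",
    intensity  = "numeric",
    normalized = "logical",
    provenance = "character"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@energy) != length(object@intensity))
      msg <- c(msg, "energy and intensity must align")
    if (is.unsorted(object@energy, strictly = TRUE))
      msg <- c(msg, "energy grid must be strictly increasing")
    if (any(object@intensity < -1e-12))
      msg <- c(msg, "intensity must be non-negative")
    if (!object@provenance %in% c("homogeneous", "inhomogeneous", "aligned"))
      msg <- c(msg, "unknown provenance")
    if (length(msg)) msg else TRUE
  }
)

#' Per-frame electronic-state observables from an MD ensemble
#'
#' One row per MD frame; excitation energies (eV) and oscillator strengths for
#' `n_states` electronic states per frame, with a dark/light state label and a
#' replica id. After bright-state selection, `s1Index`/`s2pIndex` record, per
#' frame, the first bright state (always the lowest) and the second bright
#' state S2' (the state of largest oscillator strength among states >= 2).
#'
#' @slot energies matrix, n_frames x n_states vertical excitation energies (eV).
#' @slot oscStrengths matrix, same shape, dimensionless oscillator strengths.
#' @slot state factor with levels dark/light, per frame.
#' @slot replica integer per frame (1..3 for light frames, 1 for dark).
#' @slot s1Index integer per frame (NA before selection).
#' @slot s2pIndex integer per frame (NA before selection).
#' @exportClass FrameEnsemble
setClass("FrameEnsemble",
  representation(
    energies     = "matrix",
    oscStrengths = "matrix",
    state        = "factor",
    replica      = "integer",
    s1Index      = "integer",
    s2pIndex     = "integer"
  ),
  validity = function(object) {
    msg <- character()
    nf <- nrow(object@energies)
    if (!all(dim(object@oscStrengths) == dim(object@energies)))
      msg <- c(msg, "energies and oscStrengths must have identical shape")
    if (length(object@state) != nf || length(object@replica) != nf)
      msg <- c(msg, "state and replica must have one entry per frame")
    if (!all(levels(object@state) %in% c("dark", "light")))
      msg <- c(msg, "state levels must be dark/light")
    if (any(!is.finite(object@energies)) || any(object@energies <= 0))
      msg <- c(msg, "energies must be finite and positive")
    if (length(object@s1Index) != nf || length(object@s2pIndex) != nf)
      msg <- c(msg, "selection indices must have one entry per frame")
    sel <- !is.na(object@s2pIndex)
    if (any(object@s2pIndex[sel] < 2L))
      msg <- c(msg, "S2' must be a state of index >= 2")
    if (any(object@replica[object@state == "light"] > 3L))
      msg <- c(msg, "light replica ids must be in 1..3")
    if (length(msg)) msg else TRUE
  }
)

#' Cartesian trajectory with PDB-style atom indexing
#'
#' @slot coords numeric array, n_atoms x 3 x n_frames, angstrom.
#' @slot atomNames character, PDB atom names (e.g. "CA", "OH").
#' @slot resNames character, PDB residue names (e.g. "TYR").
#' @slot resNos integer, PDB residue numbers (1-based as in the structure).
#' @slot chain character, chain identifier per atom.
#' @exportClass TrajectoryView
setClass("TrajectoryView",
  representation(
    coords    = "array",
    atomNames = "character",
    resNames  = "character",
    resNos    = "integer",
    chain     = "character"
  ),
  validity = function(object) {
    msg <- character()
    d <- dim(object@coords)
    if (length(d) != 3L || d[2] != 3L)
      msg <- c(msg, "coords must be an n_atoms x 3 x n_frames array")
    n <- d[1]
    if (length(object@atomNames) != n || length(object@resNames) != n ||
        length(object@resNos) != n || length(object@chain) != n)
      msg <- c(msg, "atom annotation must have one entry per atom")
    if (any(!is.finite(object@coords)))
      msg <- c(msg, "coordinates must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' 95% confidence interval estimate from a bootstrap
#'
#' @slot mean numeric, the plain mean of the series (or difference of means).
#' @slot lower,upper numeric, percentile bootstrap 95% CI bounds.
#' @slot nBoot integer, number of bootstrap resamples.
#' @slot seed integer, RNG seed used.
#' @exportClass IntervalEstimate
setClass("IntervalEstimate",
  representation(
    mean  = "numeric",
    lower = "numeric",
    upper = "numeric",
    nBoot = "integer",
    seed  = "integer"
  ),
  validity = function(object) {
    if (object@lower > object@mean + 1e-12 || object@upper < object@mean - 1e-12)
      "interval must bracket the mean" else TRUE
  }
)
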