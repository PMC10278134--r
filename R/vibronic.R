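#' @include AllClasses.R constants.R normal-modes.R
NULL

#' Huang-Rhys factors from an excited-state gradient (vertical gradient model)
#'
#' In the vertical-gradient approximation the excited-state surface is the
#' ground-state harmonic surface rigidly displaced along each normal mode; the
#' displacement is read off the excited-state energy gradient at the
#' ground-state minimum. Projecting the mass-weighted gradient g on mode j
#' gives the dimensionless Huang-Rhys factor S_j = g_j^2 / (2 hbar omega_j^3)
#' and the per-mode reorganization energy lambda_j = S_j hbar omega_j; the
#' total reorganization energy is their sum.
#'
#' @param gradient Cartesian excited-state gradient at the ground-state
#'   minimum, length 3N, hartree/bohr.
#' @param modes a [NormalModeSet-class] from the same geometry.
#' @return a [VibronicCoupling-class]. Modes below the mode set's
#'   low-frequency cutoff (and imaginary modes) are excluded and counted in
#'   `nExcluded`.
#' @export
vgCouplings <- function(gradient, modes) {
  stopifnot(is(modes, "NormalModeSet"))
  nAt <- length(modes@masses)
  if (length(gradient) != 3L * nAt)
    stopf("gradient length %d does not match 3N = %d",
          length(gradient), 3L * nAt)
  keep <- !modes@imaginary & modes@frequencies > modes@lowFreqCutoff
  nExcluded <- sum(!keep)
  wn <- modes@frequencies[keep]
  V <- modes@modes[, keep, drop = FALSE]
  # mass-weighted gradient in hartree / (bohr sqrt(amu))
  gmw <- gradient / rep(sqrt(modes@masses), each = 3L)
  gj <- drop(crossprod(V, gmw))
  # SI evaluation of S_j = g_j^2 / (2 hbar omega_j^3)
  gSI <- gj * physConst$hartree_J / (physConst$bohr_m * sqrt(physConst$amu_kg))
  omSI <- 2 * pi * physConst$c_cm_s * wn
  S <- gSI^2 / (2 * physConst$hbar_SI * omSI^3)
  lam <- S * wn * physConst$eV_per_cm1
  new("VibronicCoupling", frequencies = wn, hrFactors = S,
      reorgEnergies = lam, nExcluded = as.integer(nExcluded))
}

#' Construct a vibronic coupling object directly from sticks
#'
#' Convenience constructor used by fixtures and tests: supply mode
#' wavenumbers and Huang-Rhys factors directly.
#'
#' @param frequencies wavenumbers in cm^-1.
#' @param hrFactors dimensionless Huang-Rhys factors.
#' @return a [VibronicCoupling-class].
#' @export
vibronicCoupling <- function(frequencies, hrFactors) {
  new("VibronicCoupling", frequencies = as.numeric(frequencies),
      hrFactors = as.numeric(hrFactors),
      reorgEnergies = as.numeric(hrFactors * frequencies * physConst$eV_per_cm1),
      nExcluded = 0L)
}

#' Broadened spectral density from vibronic couplings
#'
#' J(omega) = pi * sum_j S_j omega_j^2 B(omega - omega_j), with B a unit-area
#' Lorentzian or Gaussian of the requested width, evaluated on a uniform
#' wavenumber grid covering `[0, 1.2 * max(omega_j)]`. The discrete sticks are
#' kept alongside the broadened curve; the sum rule
#' (1/pi) integral J(omega)/omega d omega = sum_j S_j omega_j (the
#' reorganization energy in cm^-1) ties the two representations together.
#'
#' @param coupling a [VibronicCoupling-class].
#' @param width kernel width in cm^-1 (Lorentzian HWHM or Gaussian sd); > 0.
#' @param kind "lorentzian" or "gaussian".
#' @param nGrid number of grid points.
#' @return a [SpectralDensity-class].
#' @export
buildSpectralDensity <- function(coupling, width = 5,
                                 kind = c("lorentzian", "gaussian"),
                                 nGrid = 20000L) {
  stopifnot(is(coupling, "VibronicCoupling"))
  kind <- match.arg(kind)
  if (width <= 0) stopf("width must be positive")
  if (length(coupling@frequencies) == 0L) stopf("empty coupling set")
  wmax <- 1.2 * max(coupling@frequencies)
  om <- seq(0, wmax, length.out = nGrid)
  J <- numeric(nGrid)
  for (j in seq_along(coupling@frequencies)) {
    w0 <- coupling@frequencies[j]
    S <- coupling@hrFactors[j]
    kern <- switch(kind,
      lorentzian = (width / pi) / ((om - w0)^2 + width^2),
      gaussian = stats::dnorm(om, w0, width))
    J <- J + pi * S * w0^2 * kern
  }
  new("SpectralDensity", omega = om, values = J,
      stickFreqs = coupling@frequencies, stickS = coupling@hrFactors,
      kind = kind, width = width)
}

#' Reorganization energy carried by a spectral density
#'
#' Evaluates lambda = (hbar/pi) integral J(omega)/omega d omega, either from
#' the discrete sticks (exact) or by trapezoidal quadrature of the broadened
#' grid representation.
#'
#' @param sd a [SpectralDensity-class].
#' @param from "sticks" or "grid".
#' @return reorganization energy in eV.
#' @export
reorgFromDensity <- function(sd, from = c("sticks", "grid")) {
  stopifnot(is(sd, "SpectralDensity"))
  from <- match.arg(from)
  lam_cm <- if (from == "sticks") {
    sum(sd@stickS * sd@stickFreqs)
  } else {
    integrand <- ifelse(sd@omega > 0, sd@values / sd@omega, 0)
    trapzArea(sd@omega, integrand) / pi
  }
  lam_cm * physConst$eV_per_cm1
}

#' Second-order cumulant lineshape function
#'
#' Computes g(t) = (1/pi) integral_0^inf d omega J(omega)/omega^2 *
#' (coth(hbar omega / 2 k_B T) (1 - cos omega t) + i (sin omega t - omega t)).
#' For a stick spectral density the integral reduces to the exact sum
#' g(t) = sum_j S_j (coth_j (1 - cos omega_j t) + i (sin omega_j t -
#' omega_j t)), which is the default evaluation route; `method = "grid"`
#' performs trapezoidal quadrature of the broadened J instead.
#'
#' @param sd a [SpectralDensity-class].
#' @param temperature kelvin; `0` is handled as the coth -> 1 limit.
#' @param tgrid uniform time grid in fs, starting at 0.
#' @param method "sticks" (exact) or "grid" (quadrature of the broadened J).
#' @return a [Lineshape-class].
#' @export
lineshapeG <- function(sd, temperature = 300, tgrid,
                       method = c("sticks", "grid")) {
  stopifnot(is(sd, "SpectralDensity"))
  method <- match.arg(method)
  if (temperature < 0) stopf("temperature must be >= 0")
  dt <- diff(tgrid)
  if (any(abs(dt - dt[1]) > 1e-9 * max(abs(dt))))
    stopf("time grid must be uniform")
  cothFac <- function(wn) {
    if (temperature == 0) rep(1, length(wn))
    else 1 / tanh(wn * physConst$eV_per_cm1 /
                  (2 * physConst$kB_eV * temperature))
  }
  if (method == "sticks") {
    w <- wavenumberToAngFreq(sd@stickFreqs)    # rad/fs
    S <- sd@stickS
    cth <- cothFac(sd@stickFreqs)
    wt <- outer(as.numeric(tgrid), w)          # n_t x n_modes
    g <- drop((1 - cos(wt)) %*% (S * cth)) +
      1i * (drop(sin(wt) %*% S) - as.numeric(tgrid) * sum(S * w))
  } else {
    pos <- sd@omega > 0
    om <- sd@omega[pos]
    Jv <- sd@values[pos]
    w <- wavenumberToAngFreq(om)
    cth <- cothFac(om)
    base <- Jv / om^2 / pi                      # density in cm^-1 units
    dom <- c(diff(om) / 2, 0) + c(0, diff(om) / 2)  # trapezoid weights
    g <- vapply(tgrid, function(t) {
      wt <- w * t
      sum(base * dom * (cth * (1 - cos(wt)) + 1i * (sin(wt) - wt)))
    }, complex(1))
  }
  new("Lineshape", time = as.numeric(tgrid), g = g,
      temperature = temperature)
}

#' Default uniform time grid for lineshape evaluation
#'
#' 2^15 points with the extent chosen so the damped integrand
#' `exp(-Re g(t) - gamma t / hbar)` has decayed below 1e-8 at `t_max` for the
#' given damping (pure-damping estimate), capped for numerical sanity.
#'
#' @param damping Lorentzian damping gamma in eV.
#' @param nPoints number of points (power of two recommended).
#' @param tMax optional explicit extent in fs.
#' @return numeric vector of times (fs), starting at 0.
#' @export
defaultTimeGrid <- function(damping = 1e-3, nPoints = 2^15, tMax = NULL) {
  if (is.null(tMax)) {
    gam <- max(damping, 1e-4)
    tMax <- physConst$hbar_eV_fs / gam * log(1e8)
  }
  seq(0, tMax, length.out = nPoints)
}

#' Homogeneous absorption spectrum from a cumulant lineshape
#'
#' sigma(E) proportional to Re integral_0^inf dt exp(i (E - E_vert) t / hbar
#' - g(t) - gamma t / hbar), evaluated by FFT over the lineshape time grid and
#' interpolated onto the requested energy grid; the result is normalized to
#' unit trapezoidal area. In this convention the first spectral moment equals
#' `eVert` and the 0-0 line sits at `eVert - lambda`.
#'
#' @param g a [Lineshape-class].
#' @param eVert vertical excitation energy in eV.
#' @param grid energy grid in eV; defaults to `eVert` +/- 1.5 eV at 1 meV.
#' @param damping Lorentzian damping gamma in eV (>= 0); adds a
#'   `exp(-gamma t / hbar)` factor (half-width gamma for g = 0).
#' @param areaTol raise an error when less than this fraction of the spectral
#'   area falls inside `grid`.
#' @return a normalized [Spectrum-class] with provenance "homogeneous".
#' @export
homogeneousSpectrum <- function(g, eVert, grid = NULL, damping = 1e-3,
                               areaTol = 0.999) {
  stopifnot(is(g, "Lineshape"))
  if (damping < 0) stopf("damping must be >= 0")
  if (is.null(grid))
    grid <- seq(eVert - 1.5, eVert + 1.5, by = 1e-3)
  tt <- g@time
  dt <- tt[2] - tt[1]
  hbar <- physConst$hbar_eV_fs
  f <- exp(-g@g - damping * tt / hbar)
  # half-range Fourier transform via FFT: F(E) = sum_n f(t_n) e^{+i E t_n / hbar}
  n <- length(tt)
  F <- stats::fft(f) - f[1] / 2           # trapezoid endpoint correction
  # fft frequencies k/N/dt cycles per fs -> E = -2 pi hbar k / (N dt) for the
  # forward transform; reorder to an increasing energy axis
  k <- seq_len(n) - 1
  Erel <- -2 * pi * hbar * k / (n * dt)
  Erel[Erel < -pi * hbar / dt] <- Erel[Erel < -pi * hbar / dt] + 2 * pi * hbar / dt
  ord <- order(Erel)
  Eax <- Erel[ord]
  sig <- Re(F)[ord] * dt
  sig[sig < 0] <- 0
  total <- trapzArea(Eax, sig)
  # truncation check on the native FFT axis so grid resolution cannot
  # masquerade as lost area
  inWin <- Eax >= min(grid) - eVert & Eax <= max(grid) - eVert
  inFrac <- trapzArea(Eax[inWin], sig[inWin]) / total
  if (inFrac < areaTol)
    stopf("energy grid truncates the spectrum: contains %.2f%% of the area",
          100 * inFrac)
  inGrid <- stats::approx(Eax, sig, xout = grid - eVert, rule = 2)$y
  out <- inGrid / trapzArea(grid, inGrid)
  new("Spectrum", energy = as.numeric(grid), intensity = out,
      normalized = TRUE, provenance = "homogeneous")
}

#' First spectral moment
#' @param spec a [Spectrum-class].
#' @return mean energy in eV (intensity-weighted).
#' @export
spectrumMoment <- function(spec) {
  stopifnot(is(spec, "Spectrum"))
  trapzArea(spec@energy, spec@energy * spec@intensity) /
    trapzArea(spec@energy, spec@intensity)
}
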