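#' Physical constants and unit conversions
#'
#' All internal spectroscopy computations use eV for energies, fs for times and
#' cm^-1 for vibrational wavenumbers; Hessians arrive in hartree/bohr^2,
#' gradients in hartree/bohr and masses in amu. The constants below (CODATA
#' 2018) centralise every conversion, each given to 10 significant digits.
#'
#' @format A named list:
#' \describe{
#'   \item{hartree_eV}{27.21138625 eV per hartree}
#'   \item{bohr_A}{0.5291772109 angstrom per bohr}
#'   \item{amu_kg}{1.660539067e-27 kg per amu}
#'   \item{hbar_eV_fs}{0.6582119569 eV fs (reduced Planck constant)}
#'   \item{hbar_SI}{1.054571817e-34 J s}
#'   \item{kB_eV}{8.617333262e-5 eV/K (Boltzmann constant)}
#'   \item{c_cm_s}{2.99792458e10 cm/s (speed of light)}
#'   \item{eV_per_cm1}{1.239841984e-4 eV per cm^-1 (h c)}
#'   \item{hartree_J}{4.359744722e-18 J per hartree}
#'   \item{freq_au_cm1}{5140.484532 cm^-1 per sqrt(hartree/(bohr^2 amu)):
#'     converts the square root of a mass-weighted Hessian eigenvalue to a
#'     wavenumber}
#' }
#' @export
physConst <- local({
  hartree_J <- 4.359744722e-18
  bohr_m    <- 5.291772109e-11
  amu_kg    <- 1.660539067e-27
  c_cm_s    <- 2.99792458e10
  list(
    hartree_eV  = 27.21138625,
    bohr_A      = 0.5291772109,
    amu_kg      = amu_kg,
    hbar_eV_fs  = 0.6582119569,
    hbar_SI     = 1.054571817e-34,
    kB_eV       = 8.617333262e-5,
    c_cm_s      = c_cm_s,
    c_cm_fs     = c_cm_s * 1e-15,
    eV_per_cm1  = 1.239841984e-4,
    hartree_J   = hartree_J,
    bohr_m      = bohr_m,
    # sqrt(Eh / (a0^2 amu)) in rad/s, over 2 pi c -> cm^-1
    freq_au_cm1 = sqrt(hartree_J / (bohr_m^2 * amu_kg)) / (2 * pi * c_cm_s)
  )
})

#' Convert a wavenumber to an angular frequency in rad/fs
#' @param wn wavenumber in cm^-1
#' @return angular frequency in rad/fs
#' @keywords internal
wavenumberToAngFreq <- function(wn) 2 * pi * physConst$c_cm_fs * wn

#' Evaluate an expression with a locally seeded RNG
#'
#' Saves and restores the global RNG state so that seeded generators leave no
#' footprint on the session.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Trapezoidal area of a sampled function
#' @keywords internal
trapzArea <- function(x, y) pracma::trapz(x, y)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
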