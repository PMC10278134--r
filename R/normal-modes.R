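#' @include AllClasses.R constants.R
NULL

# Mass-weighted rigid-body basis: 3 translations, plus rotations when a
# geometry is supplied (2 for linear molecules, 3 otherwise). Columns are
# orthonormalized; rank deficiencies (e.g. diatomics) are dropped.
rigidBodyBasis <- function(masses, geometry = NULL,
                           inertiaTol = 1e-6) {
  n <- length(masses)
  sm <- sqrt(masses)
  vecs <- matrix(0, 3 * n, 0)
  for (a in 1:3) {
    v <- rep(0, 3 * n)
    v[seq(a, 3 * n, by = 3)] <- sm
    vecs <- cbind(vecs, v)
  }
  nRot <- 3L
  if (!is.null(geometry)) {
    com <- colSums(geometry * masses) / sum(masses)
    rc <- sweep(geometry, 2, com)
    # inertia tensor rank decides linearity (rank 2 -> linear, 2 rotations)
    inert <- matrix(0, 3, 3)
    for (i in seq_len(n)) {
      r <- rc[i, ]
      inert <- inert + masses[i] * (sum(r^2) * diag(3) - tcrossprod(r))
    }
    ev <- eigen(inert, symmetric = TRUE, only.values = TRUE)$values
    nRot <- sum(ev > inertiaTol * max(max(ev), 1))
    for (a in 1:3) {
      axis <- diag(3)[, a]
      # apply() returns 3 x n with one column per atom; column-major
      # flattening yields the (x1, y1, z1, x2, ...) Cartesian ordering
      v <- as.vector(apply(rc, 1, function(r) pracma::cross(axis, r)))
      v <- v * rep(sm, each = 3)
      vecs <- cbind(vecs, v)
    }
  }
  q <- qr(vecs)
  basis <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  list(basis = basis, nExpected = 3L + nRot)
}

#' Normal-mode analysis of a Cartesian Hessian
#'
#' Mass-weights the Hessian (element (i,j) divided by sqrt(m_i m_j)), projects
#' out rigid translations (and rotations when `geometry` is given, with
#' linear-molecule detection by moment-of-inertia rank), diagonalizes, and
#' converts eigenvalues to wavenumbers. Negative eigenvalues are reported as
#' imaginary frequencies: the returned wavenumber is negative and the
#' `imaginary` slot flags the mode.
#'
#' @param hessian symmetric 3N x 3N Cartesian Hessian in hartree/bohr^2.
#' @param masses per-atom masses in amu.
#' @param geometry optional N x 3 matrix (bohr); enables rotational
#'   projection and linear-molecule detection.
#' @param lowFreqCutoff wavenumber (cm^-1) below which modes are excluded
#'   (default 10): near-zero modes make vertical-gradient couplings diverge.
#' @param symTol relative symmetry tolerance for the input Hessian.
#' @return a [NormalModeSet-class].
#' @export
computeModes <- function(hessian, masses, geometry = NULL,
                         lowFreqCutoff = 10, symTol = 1e-8) {
  H <- as.matrix(hessian)
  n3 <- nrow(H)
  if (ncol(H) != n3) stopf("Hessian must be square")
  if (n3 != 3L * length(masses))
    stopf("Hessian size %d does not match %d atoms", n3, length(masses))
  scale <- max(abs(H))
  if (scale == 0) stopf("degenerate input: all-zero Hessian")
  if (max(abs(H - t(H))) > symTol * scale)
    stopf("Hessian is not symmetric within tolerance %g", symTol)
  sm <- rep(sqrt(masses), each = 3L)
  Hmw <- H / outer(sm, sm)
  rb <- rigidBodyBasis(masses, geometry)
  B <- rb$basis
  P <- diag(n3) - tcrossprod(B)
  Hp <- P %*% Hmw %*% P
  Hp <- (Hp + t(Hp)) / 2
  es <- eigen(Hp, symmetric = TRUE)
  lam <- rev(es$values)           # ascending
  vec <- es$vectors[, rev(seq_len(n3)), drop = FALSE]
  wn <- sign(lam) * sqrt(abs(lam)) * physConst$freq_au_cm1
  keep <- abs(wn) > lowFreqCutoff
  # the reported projection count follows the moment-of-inertia rank when
  # geometry is available, clamped to the documented {5, 6}
  nProjected <- as.integer(min(max(rb$nExpected, 5L), 6L))
  new("NormalModeSet",
      frequencies = wn[keep],
      modes = vec[, keep, drop = FALSE],
      masses = as.numeric(masses),
      nProjected = nProjected,
      imaginary = wn[keep] < 0,
      lowFreqCutoff = lowFreqCutoff)
}

#' Identify the normal mode dominated by a given bond stretch
#'
#' Scores every mode by the magnitude of its projection onto the unit
#' bond-elongation internal coordinate of `atomPair`, expressed in
#' mass-weighted coordinates (so scores lie in `[0, 1]` against the
#' orthonormal mode basis), and returns the best-scoring mode. Used to track
#' the flavin C4=O4 carbonyl stretch across an ensemble of frame Hessians.
#'
#' @param modes a [NormalModeSet-class].
#' @param atomPair integer vector of two atom indices.
#' @param geometry N x 3 matrix giving the bond direction (any length unit).
#' @param tieTol ties in score within this tolerance are broken towards the
#'   lower frequency, with a warning.
#' @return list with `index`, `frequency` (cm^-1) and `score`.
#' @export
assignBondStretch <- function(modes, atomPair, geometry, tieTol = 1e-6) {
  stopifnot(is(modes, "NormalModeSet"))
  if (length(modes@frequencies) == 0L) stopf("empty mode set")
  if (length(atomPair) != 2L) stopf("atomPair must contain two atom indices")
  a <- atomPair[1]; b <- atomPair[2]
  nAt <- length(modes@masses)
  if (a < 1 || b < 1 || a > nAt || b > nAt || a == b)
    stopf("invalid atom pair (%s)", paste(atomPair, collapse = ", "))
  e <- geometry[b, ] - geometry[a, ]
  e <- e / sqrt(sum(e^2))
  # s = e.(x_b - x_a); in mass-weighted coordinates x = q / sqrt(m)
  u <- rep(0, 3 * nAt)
  u[(3 * (a - 1) + 1):(3 * a)] <- -e / sqrt(modes@masses[a])
  u[(3 * (b - 1) + 1):(3 * b)] <-  e / sqrt(modes@masses[b])
  u <- u / sqrt(sum(u^2))
  score <- abs(drop(crossprod(modes@modes, u)))
  best <- max(score)
  cand <- which(score >= best - tieTol)
  if (length(cand) > 1L) {
    warning("bond-stretch assignment tie; choosing the lower frequency")
    cand <- cand[which.min(modes@frequencies[cand])]
  }
  idx <- unname(cand[1])
  list(index = idx, frequency = unname(modes@frequencies[idx]),
       score = unname(score[idx]))
}
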