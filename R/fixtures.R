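#' @include AllClasses.R constants.R
NULL

#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the seeded generators that emulate the statistical
#' structure of QM/MM + MD post-processing inputs: per-state Gaussian
#' excitation-energy ensembles for a dark and a light protein state, oscillator
#' strengths with one dominant upper ("bright") state per frame, a
#' donor-hydrogen-acceptor triad with a prescribed hydrogen-bond occupancy, and
#' ideal helix geometry.
#'
#' Defaults emulate a flavin-photoreceptor ensemble: 100 dark frames and 200
#' light frames (split over three replicas); dark S1/S2' energies centred at
#' 3.20/3.95 eV and light at 3.13/3.90 eV with per-state Gaussian spreads of a
#' few hundredths of an eV, so that ensemble means carry 95% CIs of order
#' 0.005-0.01 eV at these sample sizes.
#'
#' @param seed integer RNG seed.
#' @param nFramesDark,nFramesLight frames per state label.
#' @param nStates electronic states per frame (>= 2; default 4).
#' @param energyMeans named list `dark`/`light`, each length `nStates`:
#'   per-state mean vertical excitation energies (eV). State 1 is S1; the
#'   bright upper state (S3 or S4, chosen per frame) is drawn around the S2'
#'   mean, stored as element `nStates`, while the non-bright upper state uses
#'   element `nStates - 1` shifted up by `darkStateGap`.
#' @param energySD named list `dark`/`light` of per-state Gaussian sds (eV).
#' @param brightOsc mean oscillator strength of the bright upper state.
#' @param s1Osc mean oscillator strength of S1.
#' @param oscSD sd of the bright-state oscillator strengths.
#' @param darkStateGap energy offset (eV) added to the non-bright upper state.
#' @param hbFraction target hydrogen-bond occupancy in `[0, 1]`.
#' @param helixAngle interhelical angle (degrees) for the helix-pair fixture.
#' @param sheetDihedral target dihedral (degrees) for the four-atom fixture.
#' @param nFramesTraj frames in trajectory fixtures.
#' @return a validated list of class `FixtureConfig`.
#' @export
fixtureConfig <- function(seed = 1L,
                          nFramesDark = 100L,
                          nFramesLight = 200L,
                          nStates = 4L,
                          energyMeans = list(
                            dark  = c(3.20, 3.60, 3.95, 3.95),
                            light = c(3.13, 3.55, 3.90, 3.90)),
                          energySD = list(
                            dark  = c(0.036, 0.05, 0.051, 0.051),
                            light = c(0.029, 0.05, 0.072, 0.072)),
                          brightOsc = 0.7,
                          s1Osc = 0.25,
                          oscSD = 0.05,
                          darkStateGap = 0.15,
                          hbFraction = 1.0,
                          helixAngle = 25,
                          sheetDihedral = 30,
                          nFramesTraj = 100L) {
  if (nStates < 2L)
    stopf("nStates must be >= 2 (got %d)", nStates)
  if (hbFraction < 0 || hbFraction > 1)
    stopf("hbFraction must lie in [0, 1] (got %g)", hbFraction)
  if (nFramesDark < 1L || nFramesLight < 1L || nFramesTraj < 1L)
    stopf("frame counts must be >= 1")
  for (lab in c("dark", "light")) {
    if (length(energyMeans[[lab]]) != nStates ||
        length(energySD[[lab]]) != nStates)
      stopf("energyMeans/energySD for '%s' must have length nStates", lab)
    if (any(energySD[[lab]] < 0))
      stopf("energy sds must be >= 0")
  }
  if (helixAngle < 0 || helixAngle > 180)
    stopf("helixAngle must lie in [0, 180]")
  structure(list(
    seed = as.integer(seed), nFramesDark = as.integer(nFramesDark),
    nFramesLight = as.integer(nFramesLight), nStates = as.integer(nStates),
    energyMeans = energyMeans, energySD = energySD, brightOsc = brightOsc,
    s1Osc = s1Osc, oscSD = oscSD, darkStateGap = darkStateGap,
    hbFraction = hbFraction, helixAngle = helixAngle,
    sheetDihedral = sheetDihedral, nFramesTraj = as.integer(nFramesTraj)),
    class = "FixtureConfig")
}

#' Toy Cartesian Hessian from a harmonic spring network
#'
#' Builds the analytic Hessian of a set of point masses connected by harmonic
#' bond springs: for a spring of force constant `k` along the unit bond vector
#' `u`, the 3x3 block `k * u %*% t(u)` is added to both diagonal atom blocks
#' and subtracted from the off-diagonal ones. The result is exactly symmetric
#' and translationally invariant (rows sum to zero over Cartesian blocks).
#' Units: positions in bohr, force constants in hartree/bohr^2, masses in amu.
#'
#' @param moleculeSpec list with `positions` (n x 3 matrix, bohr), `masses`
#'   (amu), and `bonds` (data.frame with columns `i`, `j`, `k`).
#' @param seed integer; seeds the optional position jitter.
#' @param jitter sd (bohr) of Gaussian noise added to positions before the
#'   Hessian is built (0 = none).
#' @return list with `hessian` (3n x 3n), `masses`, `geometry` (n x 3, bohr).
#' @export
genToyHessian <- function(moleculeSpec, seed = 1L, jitter = 0) {
  pos <- as.matrix(moleculeSpec$positions)
  masses <- as.numeric(moleculeSpec$masses)
  bonds <- moleculeSpec$bonds
  n <- nrow(pos)
  if (n < 2L) stopf("need at least 2 atoms")
  if (length(masses) != n) stopf("masses must match positions")
  if (any(bonds$k <= 0)) stopf("force constants must be positive")
  if (jitter > 0)
    pos <- withLocalSeed(seed, pos + matrix(stats::rnorm(3 * n, sd = jitter), n, 3))
  H <- matrix(0, 3 * n, 3 * n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds$i[b]; j <- bonds$j[b]; k <- bonds$k[b]
    u <- pos[j, ] - pos[i, ]
    u <- u / sqrt(sum(u^2))
    K <- k * tcrossprod(u)
    ii <- (3 * (i - 1) + 1):(3 * i)
    jj <- (3 * (j - 1) + 1):(3 * j)
    H[ii, ii] <- H[ii, ii] + K
    H[jj, jj] <- H[jj, jj] + K
    H[ii, jj] <- H[ii, jj] - K
    H[jj, ii] <- H[jj, ii] - K
  }
  list(hessian = H, masses = masses, geometry = pos)
}

#' Synthetic dark/light excitation-energy ensemble
#'
#' Draws per-frame, per-state vertical excitation energies from the Gaussians
#' configured in the [fixtureConfig()], for a dark ensemble (replica 1) and a
#' light ensemble split evenly over three replicas. Oscillator strengths are
#' drawn so that exactly one upper state (state 3 or 4, alternating at random
#' per frame) carries the dominant strength, emulating ensembles where the
#' second bright state hops between adiabatic labels from frame to frame.
#'
#' @param cfg a [fixtureConfig()].
#' @return a [FrameEnsemble-class].
#' @export
genEnergyEnsemble <- function(cfg) {
  stopifnot(inherits(cfg, "FixtureConfig"))
  ns <- cfg$nStates
  if (ns < 2L) stopf("need at least 2 electronic states")
  withLocalSeed(cfg$seed, {
    drawBlock <- function(nf, mu, sdv) {
      en <- matrix(0, nf, ns)
      f <- matrix(stats::runif(nf * ns, 0, 0.02), nf, ns)
      # which upper state is bright this frame (last two states if ns > 2)
      bright <- if (ns > 2L) sample(c(ns - 1L, ns), nf, replace = TRUE)
                else rep(ns, nf)
      for (s in seq_len(ns))
        en[, s] <- stats::rnorm(nf, mu[s], sdv[s])
      if (ns > 2L) {
        # non-bright upper partner sits darkStateGap above the bright mean
        other <- ifelse(bright == ns, ns - 1L, ns)
        en[cbind(seq_len(nf), other)] <-
          stats::rnorm(nf, mu[ns] + cfg$darkStateGap, sdv[ns])
      }
      f[, 1] <- pmax(stats::rnorm(nf, cfg$s1Osc, cfg$oscSD / 2), 0.05)
      f[cbind(seq_len(nf), bright)] <-
        pmax(stats::rnorm(nf, cfg$brightOsc, cfg$oscSD), 0.1)
      # sort each frame's energies so state index tracks energetic order
      ord <- t(apply(en, 1, order))
      for (r in seq_len(nf)) {
        en[r, ] <- en[r, ord[r, ]]
        f[r, ] <- f[r, ord[r, ]]
      }
      list(en = en, f = f)
    }
    d <- drawBlock(cfg$nFramesDark, cfg$energyMeans$dark, cfg$energySD$dark)
    l <- drawBlock(cfg$nFramesLight, cfg$energyMeans$light, cfg$energySD$light)
    nl <- cfg$nFramesLight
    repl <- c(rep(1L, cfg$nFramesDark),
              rep_len(rep(1:3, each = ceiling(nl / 3)), nl))
    new("FrameEnsemble",
        energies = rbind(d$en, l$en),
        oscStrengths = rbind(d$f, l$f),
        state = factor(rep(c("dark", "light"),
                           c(cfg$nFramesDark, nl)), levels = c("dark", "light")),
        replica = repl,
        s1Index = rep(NA_integer_, cfg$nFramesDark + nl),
        s2pIndex = rep(NA_integer_, cfg$nFramesDark + nl))
  })
}

#' Donor-hydrogen-acceptor trajectory with a prescribed H-bond occupancy
#'
#' Builds a three-atom triad (Tyr-like donor OH/HH and a Gln-like NE2
#' acceptor) whose geometry satisfies the standard hydrogen-bond criterion
#' (donor-acceptor distance <= 3.2 A and donor-hydrogen...acceptor angle >=
#' 135 deg) in exactly `round(hbFraction * nFramesTraj)` frames. Bonded frames
#' use d(D,A) = 2.8 A, broken frames 3.6 A, both collinear, i.e. at least
#' 0.4 A away from the distance cutoff so occupancy is robust to small cutoff
#' changes. Which frames are bonded is a seeded permutation.
#'
#' @param cfg a [fixtureConfig()].
#' @return a [TrajectoryView-class]; the constructed per-frame bond indicator
#'   is attached as attribute `"bonded"`.
#' @export
genHBondTrajectory <- function(cfg) {
  stopifnot(inherits(cfg, "FixtureConfig"))
  nf <- cfg$nFramesTraj
  nBond <- round(cfg$hbFraction * nf)
  bonded <- withLocalSeed(cfg$seed,
    seq_len(nf) %in% sample.int(nf, nBond))
  xyz <- array(0, dim = c(3, 3, nf))
  for (t in seq_len(nf)) {
    dDA <- if (bonded[t]) 2.8 else 3.6
    xyz[1, , t] <- c(0, 0, 0)        # donor OH
    xyz[2, , t] <- c(1.0, 0, 0)      # hydrogen HH
    xyz[3, , t] <- c(dDA, 0, 0)      # acceptor NE2
  }
  out <- new("TrajectoryView", coords = xyz,
             atomNames = c("OH", "HH", "NE2"),
             resNames = c("TYR", "TYR", "GLN"),
             resNos = c(21L, 21L, 63L),
             chain = c("A", "A", "A"))
  attr(out, "bonded") <- bonded
  out
}

idealHelixTrace <- function(nRes, radius = 2.3, rise = 1.5, twist = 100) {
  i <- seq_len(nRes) - 1
  ph <- i * twist * pi / 180
  cbind(radius * cos(ph), radius * sin(ph), rise * i)
}

rotationY <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3)
}

#' Pair of ideal alpha-helical C-alpha traces at a set interhelical angle
#'
#' Two canonical alpha-helix traces (rise 1.5 A/residue, 100 deg twist, radius
#' 2.3 A) of `nRes` residues each; the second helix axis is rotated by `angle`
#' degrees relative to the first and displaced laterally. With the default 22
#' residues the four-C-alpha terminal windows used by [interhelicalAngle()]
#' are separated by 18 residues, i.e. an exact multiple of the 3.6-residue
#' helical repeat, so the centroid-difference axis reproduces the true helix
#' axis and the constructed angle is recovered essentially exactly.
#'
#' @param angle interhelical angle in degrees, in `[0, 180]`.
#' @param nRes residues per helix (>= 8).
#' @param nFrames number of (identical) frames.
#' @return a [TrajectoryView-class] of C-alpha atoms; helix 1 has residues
#'   1..nRes (chain A), helix 2 residues 101..(100+nRes) (chain B).
#' @export
genHelixPair <- function(angle, nRes = 22L, nFrames = 1L) {
  if (angle < 0 || angle > 180) stopf("angle must lie in [0, 180]")
  if (nRes < 8L) stopf("need >= 8 residues per helix")
  h1 <- idealHelixTrace(nRes)
  h2 <- idealHelixTrace(nRes) %*% t(rotationY(angle))
  h2 <- sweep(h2, 2, c(15, 0, 0), "+")
  xyz0 <- rbind(h1, h2)
  n <- nrow(xyz0)
  xyz <- array(rep(t(xyz0), nFrames), dim = c(3, n, nFrames))
  xyz <- aperm(xyz, c(2, 1, 3))
  new("TrajectoryView", coords = xyz,
      atomNames = rep("CA", n),
      resNames = rep("ALA", n),
      resNos = c(seq_len(nRes), 100L + seq_len(nRes)),
      chain = rep(c("A", "B"), each = nRes))
}

#' Four-atom quadruple at a prescribed dihedral angle
#'
#' Builds a trajectory of four atoms whose signed torsion equals `angle`
#' degrees by construction: the central bond lies along z and the outer atoms
#' are placed in half-planes rotated by the requested torsion.
#'
#' @param angle target dihedral in degrees, in `(-180, 180]`.
#' @param nFrames number of (identical) frames.
#' @return a [TrajectoryView-class] of four CA atoms (residues 18, 50, 59, 89).
#' @export
genDihedralQuad <- function(angle, nFrames = 1L) {
  th <- angle * pi / 180
  xyz0 <- rbind(c(1.5, 0, -1.5),
                c(0, 0, 0),
                c(0, 0, 1.5),
                c(1.5 * cos(th), 1.5 * sin(th), 3.0))
  xyz <- array(rep(t(xyz0), nFrames), dim = c(3, 4, nFrames))
  xyz <- aperm(xyz, c(2, 1, 3))
  new("TrajectoryView", coords = xyz,
      atomNames = rep("CA", 4),
      resNames = c("SER", "LEU", "GLY", "GLU"),
      resNos = c(18L, 50L, 59L, 89L),
      chain = rep("A", 4))
}

#' Gaussian scalar observable series (chemical shifts, mode frequencies)
#'
#' Convenience generator for per-frame scalar observables used by the
#' bootstrap statistics: i.i.d. Gaussian draws at a configured mean and sd.
#'
#' @param mean,sd Gaussian parameters (observable units).
#' @param n number of frames.
#' @param seed integer seed.
#' @param label observable label (e.g. "FMN H3 shift (ppm)").
#' @param state "dark" or "light".
#' @param replica replica id.
#' @return data.frame with columns frame, value, label, state, replica.
#' @export
genObservableSeries <- function(mean, sd, n, seed = 1L, label = "obs",
                                state = c("dark", "light"), replica = 1L) {
  state <- match.arg(state)
  v <- withLocalSeed(seed, stats::rnorm(n, mean, sd))
  data.frame(frame = seq_len(n), value = v, label = label,
             state = state, replica = as.integer(replica),
             stringsAsFactors = FALSE)
}
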