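#' @include AllClasses.R
NULL

#' Read a PDB file into a single-frame trajectory
#'
#' Thin wrapper over [bio3d::read.pdb()] exposing the package's
#' [TrajectoryView-class] container. Insertion codes are rejected: residue
#' numbering must be plain.
#'
#' @param path PDB file path.
#' @return a [TrajectoryView-class] with one frame.
#' @export
readPDB <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  if (any(nzchar(trimws(at$insert)) & !is.na(at$insert)))
    stopf("insertion codes are not supported (file %s)", path)
  n <- nrow(at)
  xyz <- array(as.matrix(at[, c("x", "y", "z")]), dim = c(n, 3, 1))
  new("TrajectoryView", coords = xyz,
      atomNames = as.character(at$elety),
      resNames = as.character(at$resid),
      resNos = as.integer(at$resno),
      chain = ifelse(is.na(at$chain), "A", as.character(at$chain)))
}

#' Write a trajectory's topology (+ first frame) as PDB
#'
#' @param traj a [TrajectoryView-class].
#' @param path output path.
#' @param frame which frame's coordinates to write.
#' @return `path`, invisibly.
#' @export
writePDB <- function(traj, path, frame = 1L) {
  stopifnot(is(traj, "TrajectoryView"))
  n <- nAtoms(traj)
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(traj@coords[, , frame])),
                   resno = traj@resNos,
                   resid = traj@resNames,
                   eleno = seq_len(n),
                   elety = traj@atomNames,
                   chain = traj@chain)
  invisible(path)
}

#' Read a multi-frame XYZ trajectory
#'
#' Plain multi-frame XYZ: each frame is an atom count line, a comment line,
#' then `n` lines of `name x y z`. The atom count must be constant across
#' frames. Atom metadata (residue names/numbers) can be supplied from a
#' matching topology.
#'
#' @param path XYZ file path.
#' @param topology optional [TrajectoryView-class] supplying atom/residue
#'   annotation (atom count must match).
#' @return a [TrajectoryView-class].
#' @export
readXYZTrajectory <- function(path, topology = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  frames <- list()
  names1 <- NULL
  i <- 1L
  frameNo <- 0L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    frameNo <- frameNo + 1L
    if (is.na(n) || n < 1L)
      stopf("frame %d: bad atom count line %d ('%s')", frameNo, i, lines[i])
    if (i + 1L + n > length(lines))
      stopf("frame %d: truncated (expected %d atoms)", frameNo, n)
    block <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(block), "\\s+")
    nm <- vapply(toks, `[`, character(1), 1L)
    co <- t(vapply(toks, function(tk) as.numeric(tk[2:4]), numeric(3)))
    if (any(!is.finite(co)))
      stopf("frame %d: non-numeric coordinates", frameNo)
    if (is.null(names1)) names1 <- nm
    else if (length(nm) != length(names1))
      stopf("frame %d: atom count %d differs from first frame %d",
            frameNo, length(nm), length(names1))
    frames[[frameNo]] <- co
    i <- i + 2L + n
  }
  nAt <- length(names1)
  xyz <- array(0, dim = c(nAt, 3, length(frames)))
  for (t in seq_along(frames)) xyz[, , t] <- frames[[t]]
  if (!is.null(topology)) {
    if (nAtoms(topology) != nAt)
      stopf("topology has %d atoms, trajectory %d", nAtoms(topology), nAt)
    new("TrajectoryView", coords = xyz, atomNames = topology@atomNames,
        resNames = topology@resNames, resNos = topology@resNos,
        chain = topology@chain)
  } else {
    new("TrajectoryView", coords = xyz, atomNames = names1,
        resNames = rep("UNK", nAt), resNos = seq_len(nAt),
        chain = rep("A", nAt))
  }
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj a [TrajectoryView-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeXYZTrajectory <- function(traj, path) {
  stopifnot(is(traj, "TrajectoryView"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nAtoms(traj)
  for (t in seq_len(nFrames(traj))) {
    writeLines(c(as.character(n), sprintf("frame %d", t)), con)
    writeLines(sprintf("%-4s %14.8f %14.8f %14.8f", traj@atomNames,
                       traj@coords[, 1, t], traj@coords[, 2, t],
                       traj@coords[, 3, t]), con)
  }
  invisible(path)
}

#' Read per-frame QM records from JSON
#'
#' Documented plain-JSON fixture format for QM outputs: a list of frame
#' records, each with `frequencies_cm1`, `modes` (3N x n_modes, column-major
#' list of columns), `masses_amu`, `gradient_hartree_bohr` (per excited
#' state), `energies_eV` and `osc_strengths`.
#'
#' @param path JSON file path.
#' @return list of frame records.
#' @export
readQMRecords <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}

#' Write per-frame QM records as JSON
#'
#' @param records list of frame records (see [readQMRecords()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeQMRecords <- function(records, path) {
  jsonlite::write_json(records, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write a spectrum as a two-column CSV
#'
#' @param spec a [Spectrum-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpectrumCSV <- function(spec, path) {
  stopifnot(is(spec, "Spectrum"))
  utils::write.csv(data.frame(energy_eV = spec@energy,
                              intensity = spec@intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a two-column spectrum CSV
#'
#' @param path CSV with columns energy_eV, intensity.
#' @param provenance provenance tag for the resulting object.
#' @return a [Spectrum-class].
#' @export
readSpectrumCSV <- function(path, provenance = "homogeneous") {
  d <- utils::read.csv(path)
  new("Spectrum", energy = d$energy_eV, intensity = d$intensity,
      normalized = abs(trapzArea(d$energy_eV, d$intensity) - 1) < 1e-6,
      provenance = provenance)
}

#' Read the pipeline run configuration
#'
#' Plain-text YAML key-value configuration; every parameter carries a default
#' (hydrogen-bond cutoffs 3.2 A / 135 deg, three light replicas, 95% CIs,
#' temperature 300 K, damping 1 meV, n_boot 2000) so a minimal file needs
#' only the entries it overrides.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @param overrides named list merged over the file values.
#' @return a named list of class `RunConfig`.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  defaults <- list(
    seed = 1L,
    outputDir = "blufspec-out",
    nFramesDark = 100L, nFramesLight = 200L, nStates = 4L,
    temperatureK = 300, dampingEV = 1e-3, sdWidthCM = 5,
    nBoot = 2000L,
    hbDistCutoff = 3.2, hbAngleCutoff = 135,
    gridStepEV = 1e-3,
    # observable-series generator settings (mean, sd, per state)
    h3ShiftDark = c(11.6, 1.0), h3ShiftLight = c(11.9, 0.72),
    coFreqDark = c(1753, 15.3), coFreqLight = c(1727, 14.4),
    hbFractionDark = 0.30, hbFractionLight = 0.95,
    helixAngleDark = 20, helixAngleLight = 25)
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("no such config file: %s", path)
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "RunConfig")
}
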