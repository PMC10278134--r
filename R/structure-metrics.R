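#' @include AllClasses.R constants.R
NULL

#' Resolve a PDB-style atom selector to one atom index
#'
#' Selectors are strings of the form `"<resno>@<atomname>"` (e.g. `"21@OH"`)
#' or lists `list(resno =, name =, chain =)`; they must resolve to exactly one
#' atom.
#'
#' @param traj a [TrajectoryView-class].
#' @param sel selector string or list.
#' @return integer atom index.
#' @export
resolveSelector <- function(traj, sel) {
  stopifnot(is(traj, "TrajectoryView"))
  if (is.character(sel) && length(sel) == 1L) {
    parts <- strsplit(sel, "@", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stopf("selector '%s' is not of the form resno@atomname", sel)
    sel <- list(resno = as.integer(parts[1]), name = parts[2])
  }
  hit <- traj@resNos == sel$resno & traj@atomNames == sel$name
  if (!is.null(sel$chain)) hit <- hit & traj@chain == sel$chain
  ix <- which(hit)
  if (length(ix) != 1L)
    stopf("selector '%s@%s' resolves to %d atoms (need exactly 1)",
          sel$resno, sel$name, length(ix))
  ix
}

#' Hydrogen-bond criterion specification
#'
#' Standard geometric criterion: donor-acceptor distance below `distCutoff`
#' and the angle at the configurable vertex atom above `angleCutoff`. The
#' conventional pairing of these default cutoff values places the vertex at
#' the hydrogen (D-H...A angle); the vertex is configurable because published
#' phrasings of the angle criterion are sometimes ambiguous.
#'
#' @param donor,hydrogen,acceptor atom selectors (see [resolveSelector()]).
#' @param distCutoff donor-acceptor distance cutoff in angstrom (default 3.2).
#' @param angleCutoff angle cutoff in degrees (default 135).
#' @param vertex which atom the angle is measured at: "hydrogen" (D-H...A,
#'   default), "acceptor" or "donor".
#' @return an object of class `HBondSpec` (list).
#' @export
hbondSpec <- function(donor, hydrogen, acceptor,
                      distCutoff = 3.2, angleCutoff = 135,
                      vertex = c("hydrogen", "acceptor", "donor")) {
  vertex <- match.arg(vertex)
  if (distCutoff <= 0 || angleCutoff <= 0 || angleCutoff > 180)
    stopf("cutoffs must be positive and angle cutoff <= 180")
  structure(list(donor = donor, hydrogen = hydrogen, acceptor = acceptor,
                 distCutoff = distCutoff, angleCutoff = angleCutoff,
                 vertex = vertex),
            class = "HBondSpec")
}

angleAt <- function(vertexPt, p1, p2) {
  v1 <- p1 - vertexPt
  v2 <- p2 - vertexPt
  cosA <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(pmax(cosA, -1), 1)) * 180 / pi
}

#' Hydrogen-bond occupancy along a trajectory
#'
#' A frame counts as bonded when the donor-acceptor distance is at most the
#' distance cutoff AND the angle at the spec's vertex atom is at least the
#' angle cutoff; occupancy is the bonded fraction of frames.
#'
#' @param traj a [TrajectoryView-class].
#' @param spec an [hbondSpec()].
#' @return list with `occupancy` and the per-frame logical series `bonded`.
#' @export
hbondOccupancy <- function(traj, spec) {
  stopifnot(is(traj, "TrajectoryView"), inherits(spec, "HBondSpec"))
  iD <- resolveSelector(traj, spec$donor)
  iH <- resolveSelector(traj, spec$hydrogen)
  iA <- resolveSelector(traj, spec$acceptor)
  nf <- nFrames(traj)
  bonded <- logical(nf)
  for (t in seq_len(nf)) {
    D <- traj@coords[iD, , t]
    H <- traj@coords[iH, , t]
    A <- traj@coords[iA, , t]
    dDA <- sqrt(sum((D - A)^2))
    ang <- switch(spec$vertex,
      hydrogen = angleAt(H, D, A),
      acceptor = angleAt(A, H, D),
      donor    = angleAt(D, H, A))
    bonded[t] <- dDA <= spec$distCutoff && ang >= spec$angleCutoff
  }
  list(occupancy = mean(bonded), bonded = bonded)
}

#' Interhelical-angle specification
#'
#' Each helix vector is defined by four consecutive C-alpha atoms at the
#' start and four at the end of the helix; the vector points from the
#' centroid of the start window to the centroid of the end window.
#'
#' @param helix1Start,helix1End,helix2Start,helix2End integer vectors of four
#'   residue numbers each (resolved to CA atoms).
#' @return an object of class `HelixVectorSpec` (list).
#' @export
helixVectorSpec <- function(helix1Start, helix1End, helix2Start, helix2End) {
  for (w in list(helix1Start, helix1End, helix2Start, helix2End))
    if (length(w) != 4L) stopf("each helix window needs exactly 4 residues")
  structure(list(h1s = helix1Start, h1e = helix1End,
                 h2s = helix2Start, h2e = helix2End),
            class = "HelixVectorSpec")
}

caCentroid <- function(traj, resnos, t) {
  ix <- vapply(resnos, function(r)
    resolveSelector(traj, list(resno = r, name = "CA")), integer(1))
  colMeans(traj@coords[ix, , t, drop = FALSE][, , 1])
}

#' Interhelical angle per frame
#'
#' Per helix the axis vector runs from the centroid of its four start C-alpha
#' atoms to the centroid of its four end C-alpha atoms; the interhelical angle
#' is the unsigned angle between the two axis vectors, in `[0, 180]` degrees.
#'
#' @param traj a [TrajectoryView-class].
#' @param spec a [helixVectorSpec()].
#' @return numeric vector of per-frame angles (degrees).
#' @export
interhelicalAngle <- function(traj, spec) {
  stopifnot(is(traj, "TrajectoryView"), inherits(spec, "HelixVectorSpec"))
  nf <- nFrames(traj)
  vapply(seq_len(nf), function(t) {
    v1 <- caCentroid(traj, spec$h1e, t) - caCentroid(traj, spec$h1s, t)
    v2 <- caCentroid(traj, spec$h2e, t) - caCentroid(traj, spec$h2s, t)
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 < 1e-9 || n2 < 1e-9) stopf("degenerate helix axis (zero length)")
    acos(pmin(pmax(sum(v1 * v2) / (n1 * n2), -1), 1)) * 180 / pi
  }, numeric(1))
}

torsionAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma::cross(b1, b2)
  n2 <- pracma::cross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-6 || sqrt(sum(n2^2)) < 1e-6)
    stopf("degenerate geometry: collinear atom triple in dihedral")
  x <- sum(n1 * n2)
  y <- sum(pracma::cross(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

#' Signed dihedral over four C-alpha atoms, per frame
#'
#' Standard signed torsion (right-hand convention) of the ordered atom
#' quadruple, in degrees in `(-180, 180]`; used to quantify beta-sheet
#' twisting via four corner C-alpha atoms.
#'
#' @param traj a [TrajectoryView-class].
#' @param selectors list of four atom selectors (see [resolveSelector()]).
#' @return numeric vector of per-frame dihedrals (degrees).
#' @export
sheetDihedral <- function(traj, selectors) {
  stopifnot(is(traj, "TrajectoryView"))
  if (length(selectors) != 4L) stopf("need exactly four atom selectors")
  ix <- vapply(selectors, function(s) resolveSelector(traj, s), integer(1))
  if (anyDuplicated(ix)) stopf("dihedral atoms must be distinct")
  vapply(seq_len(nFrames(traj)), function(t) {
    torsionAngle(traj@coords[ix[1], , t], traj@coords[ix[2], , t],
                 traj@coords[ix[3], , t], traj@coords[ix[4], , t])
  }, numeric(1))
}

# Kabsch least-squares rotation R minimizing |x R - y| (both centred n x 3)
kabschRotation <- function(x, y) {
  s <- svd(crossprod(x, y))
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Backbone RMSD to a reference frame after optimal superposition
#'
#' Selects backbone atoms (N, CA, C, O by default), optionally excluding
#' flexible residue spans, superposes every frame onto the reference frame by
#' the least-squares (Kabsch) rotation and reports the per-frame RMSD in
#' angstrom.
#'
#' @param traj a [TrajectoryView-class].
#' @param refFrame index of the reference frame (default 1).
#' @param backboneNames atom names treated as backbone.
#' @param excludeResidues integer vector of residue numbers to exclude
#'   (flexible spans; e.g. `c(1:5, 120:126)`).
#' @return numeric vector of per-frame RMSD values (angstrom).
#' @export
backboneRMSD <- function(traj, refFrame = 1L,
                         backboneNames = c("N", "CA", "C", "O"),
                         excludeResidues = integer(0)) {
  stopifnot(is(traj, "TrajectoryView"))
  sel <- traj@atomNames %in% backboneNames &
         !(traj@resNos %in% excludeResidues)
  if (!any(sel)) stopf("backbone selection is empty")
  ref <- traj@coords[sel, , refFrame, drop = FALSE][, , 1]
  refC <- sweep(ref, 2, colMeans(ref))
  vapply(seq_len(nFrames(traj)), function(t) {
    x <- traj@coords[sel, , t, drop = FALSE][, , 1]
    xC <- sweep(x, 2, colMeans(x))
    rot <- kabschRotation(xC, refC)
    d <- xC %*% rot - refC
    sqrt(mean(rowSums(d^2)))
  }, numeric(1))
}

#' Normalized histograms of metric series with shared binning
#'
#' @param seriesList named list of numeric series (e.g. one per state or
#'   replica).
#' @param bins number of bins shared across all series.
#' @return data.frame with columns series, mid, density.
#' @export
metricDistributions <- function(seriesList, bins = 40L) {
  if (!length(seriesList)) stopf("no series supplied")
  rng <- range(unlist(seriesList))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  do.call(rbind, lapply(names(seriesList), function(nm) {
    h <- graphics::hist(seriesList[[nm]], breaks = breaks, plot = FALSE)
    data.frame(series = nm, mid = h$mids, density = h$density,
               stringsAsFactors = FALSE)
  }))
}

#' Apply a rigid motion (rotation + translation) to every frame
#'
#' Utility for invariance checks and fixture construction.
#'
#' @param traj a [TrajectoryView-class].
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector (angstrom).
#' @return the transformed [TrajectoryView-class].
#' @export
rigidTransform <- function(traj, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is(traj, "TrajectoryView"))
  out <- traj
  for (t in seq_len(nFrames(traj))) {
    out@coords[, , t] <- sweep(traj@coords[, , t] %*% t(rotation), 2,
                               translation, "+")
  }
  out
}
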