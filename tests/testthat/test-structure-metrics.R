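hbTriad <- function(dDA = 2.8, angle = 180) {
  # donor at origin, hydrogen 1 A along x; acceptor placed so the D-H...A
  # angle at the hydrogen equals `angle` and d(D,A) = dDA
  th <- (180 - angle) * pi / 180
  r <- dDA  # solve acceptor on the cone around H
  # place A in the xy-plane at distance from H chosen to match d(D,A)
  # simple construction: A = H + t * (cos th, sin th, 0); find t
  f <- function(t) sqrt((1 + t * cos(th))^2 + (t * sin(th))^2) - r
  t <- stats::uniroot(f, c(0.1, 10))$root
  A <- c(1 + t * cos(th), t * sin(th), 0)
  xyz <- array(0, c(3, 3, 1))
  xyz[1, , 1] <- c(0, 0, 0); xyz[2, , 1] <- c(1, 0, 0); xyz[3, , 1] <- A
  new("TrajectoryView", coords = xyz, atomNames = c("OH", "HH", "NE2"),
      resNames = c("TYR", "TYR", "GLN"), resNos = c(21L, 21L, 63L),
      chain = rep("A", 3))
}

test_that("hydrogen-bond criterion applies both cutoffs", {
  spec <- hbondSpec("21@OH", "21@HH", "63@NE2")
  expect_equal(hbondOccupancy(hbTriad(2.8, 180), spec)$occupancy, 1)
  expect_equal(hbondOccupancy(hbTriad(3.5, 180), spec)$occupancy, 0)
  expect_equal(hbondOccupancy(hbTriad(2.8, 120), spec)$occupancy, 0)
  expect_equal(hbondOccupancy(hbTriad(2.8, 140), spec)$occupancy, 1)
  expect_error(hbondOccupancy(hbTriad(), hbondSpec("21@OG", "21@HH", "63@NE2")),
               "21@OG")
})

test_that("constructed 37% occupancy is recovered exactly", {
  tr <- genHBondTrajectory(fixtureConfig(seed = 9L, hbFraction = 0.37,
                                         nFramesTraj = 100L))
  spec <- hbondSpec("21@OH", "21@HH", "63@NE2")
  expect_equal(hbondOccupancy(tr, spec)$occupancy, 0.37)
  expect_equal(hbondOccupancy(tr, spec)$bonded, attr(tr, "bonded"))
})

test_that("interhelical angles recover translations, reflections and constructions", {
  spec <- helixVectorSpec(1:4, 19:22, 101:104, 119:122)
  # two copies of one helix translated: 0 degrees
  h <- genHelixPair(0)
  expect_equal(interhelicalAngle(h, spec), 0, tolerance = 1e-8)
  # axis flip: 180 degrees
  h180 <- genHelixPair(180)
  expect_equal(interhelicalAngle(h180, spec), 180, tolerance = 1e-8)
  expect_lt(abs(interhelicalAngle(genHelixPair(25), spec) - 25), 2)
})

test_that("dihedrals match the triple-product oracle and flip under mirroring", {
  sel <- list("18@CA", "50@CA", "59@CA", "89@CA")
  set.seed(77)
  for (rep in 1:10) {
    xyz <- array(rnorm(12, sd = 3), c(4, 3, 1))
    tr <- new("TrajectoryView", coords = xyz, atomNames = rep("CA", 4),
              resNames = c("SER", "LEU", "GLY", "GLU"),
              resNos = c(18L, 50L, 59L, 89L), chain = rep("A", 4))
    got <- sheetDihedral(tr, sel)
    want <- torsionOracle(xyz[1, , 1], xyz[2, , 1], xyz[3, , 1], xyz[4, , 1])
    expect_equal(got, want, tolerance = 1e-8)
    # mirror reflection (z -> -z) flips the sign
    trM <- tr; trM@coords[, 3, ] <- -trM@coords[, 3, ]
    expect_equal(sheetDihedral(trM, sel), -got, tolerance = 1e-8)
  }
  # canonical quadruple: right-hand convention gives -90
  xyz <- array(t(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1))),
               c(3, 4, 1))
  tr <- new("TrajectoryView", coords = aperm(xyz, c(2, 1, 3)),
            atomNames = rep("CA", 4), resNames = rep("GLY", 4),
            resNos = c(18L, 50L, 59L, 89L), chain = rep("A", 4))
  got <- sheetDihedral(tr, sel)
  expect_equal(abs(got), 90, tolerance = 1e-10)
  expect_equal(got, torsionOracle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                                  c(1, 1, 1)))
  # collinear triple is degenerate
  bad <- tr; bad@coords[3, , 1] <- c(2, 0, 0)
  expect_error(sheetDihedral(bad, sel), "collinear")
})

test_that("all metrics are invariant under rigid motions", {
  set.seed(55)
  hb <- genHBondTrajectory(fixtureConfig(seed = 2L, hbFraction = 0.4,
                                         nFramesTraj = 20L))
  hel <- genHelixPair(25, nFrames = 2L)
  quad <- genDihedralQuad(35, nFrames = 2L)
  hbS <- hbondSpec("21@OH", "21@HH", "63@NE2")
  helS <- helixVectorSpec(1:4, 19:22, 101:104, 119:122)
  diS <- list("18@CA", "50@CA", "59@CA", "89@CA")
  for (rep in 1:3) {
    R <- randomRotation(); tvec <- rnorm(3, sd = 20)
    expect_equal(hbondOccupancy(rigidTransform(hb, R, tvec), hbS)$bonded,
                 hbondOccupancy(hb, hbS)$bonded)
    expect_equal(interhelicalAngle(rigidTransform(hel, R, tvec), helS),
                 interhelicalAngle(hel, helS), tolerance = 1e-8)
    expect_equal(sheetDihedral(rigidTransform(quad, R, tvec), diS),
                 sheetDihedral(quad, diS), tolerance = 1e-8)
  }
})

test_that("backbone RMSD removes rigid motion and matches the closed form", {
  set.seed(65)
  n <- 100L
  x <- matrix(rnorm(3 * n, sd = 8), n, 3)
  x <- sweep(x, 2, colMeans(x))
  R <- randomRotation(); tvec <- c(5, -3, 11)
  y <- sweep(x %*% t(R), 2, tvec, "+")
  i0 <- which.min(rowSums(x^2))   # atom nearest the centroid
  z <- x; z[i0, ] <- z[i0, ] + c(1, 0, 0)
  xyz <- array(0, c(n, 3, 3))
  xyz[, , 1] <- x; xyz[, , 2] <- y; xyz[, , 3] <- z
  tr <- new("TrajectoryView", coords = xyz, atomNames = rep("CA", n),
            resNames = rep("ALA", n), resNos = seq_len(n),
            chain = rep("A", n))
  r <- backboneRMSD(tr)
  expect_equal(r[1], 0)
  expect_lt(r[2], 1e-8)                       # pure rigid motion
  expect_equal(r[3], sqrt(1 / n), tolerance = 0.01)  # single 1 A displacement
  # independent cross-check against the bio3d superposition machinery
  fitted <- suppressWarnings(bio3d::fit.xyz(as.vector(t(x)), as.vector(t(z))))
  oracle <- sqrt(mean(colSums(matrix((fitted - as.vector(t(x)))^2, nrow = 3))))
  expect_equal(r[3], oracle, tolerance = 1e-8)
})

test_that("flexible-span exclusion and selection errors behave", {
  hel <- genHelixPair(25)
  rAll <- backboneRMSD(hel, backboneNames = "CA")
  rCut <- backboneRMSD(hel, backboneNames = "CA",
                       excludeResidues = c(1:4, 119:122))
  expect_equal(rAll[1], 0)
  expect_equal(rCut[1], 0)
  expect_error(backboneRMSD(hel, backboneNames = "CB"), "empty")
})

test_that("metric distributions share binning and recover sample structure", {
  set.seed(71)
  a <- rnorm(4000, 20, 2); b <- rnorm(4000, 25, 2)
  d <- metricDistributions(list(dark = a, light = b), bins = 50L)
  expect_setequal(unique(d$series), c("dark", "light"))
  expect_equal(unique(table(d$series)), 50L)
  mDark <- with(d[d$series == "dark", ], sum(mid * density) / sum(density))
  expect_lt(abs(mDark - 20), 3 * 2 / sqrt(4000) + diff(range(a)) / 50)
  # identical series give identical histograms
  d2 <- metricDistributions(list(x = a, y = a))
  expect_equal(d2$density[d2$series == "x"], d2$density[d2$series == "y"])
})
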