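test_that("bright-state selection follows the largest oscillator strength", {
  mk <- function(en, f) {
    new("FrameEnsemble", energies = matrix(en, 1), oscStrengths = matrix(f, 1),
        state = factor("dark", levels = c("dark", "light")), replica = 1L,
        s1Index = NA_integer_, s2pIndex = NA_integer_)
  }
  e1 <- selectBrightStates(mk(c(3.0, 3.5, 3.9, 4.1), c(0.2, 0.0, 0.3, 0.1)))
  expect_equal(e1@s2pIndex, 3L)
  e2 <- selectBrightStates(mk(c(3.0, 3.5, 3.9, 4.1), c(0.2, 0.0, 0.1, 0.3)))
  expect_equal(e2@s2pIndex, 4L)
  expect_equal(e2@s1Index, 1L)
  # tie resolves to the lower-energy state with a warning
  expect_warning(
    et <- selectBrightStates(mk(c(3.0, 3.5, 3.9, 4.1), c(0.2, 0.0, 0.3, 0.3))),
    "tie")
  expect_equal(et@s2pIndex, 3L)
})

test_that("per-frame selections match an exhaustive argmax oracle", {
  ens <- genEnergyEnsemble(fixtureConfig(seed = 23L, nFramesDark = 100L,
                                         nFramesLight = 100L))
  sel <- selectBrightStates(ens)
  f <- oscStrengths(ens)
  oracle <- vapply(seq_len(nrow(f)), function(r) {
    cand <- 2:ncol(f)
    cand[which.max(f[r, cand])]
  }, integer(1))
  expect_equal(sel@s2pIndex, oracle)
  # both upper states get picked across the ensemble
  expect_setequal(unique(sel@s2pIndex), c(3L, 4L))
  expect_error(bandEnergies(ens, "S2p"), "missing")
})

test_that("a single frame reproduces the homogeneous line at its energy", {
  grid <- seq(2.0, 4.5, by = 1e-3)
  hom <- gaussianSpectrum(grid, 3.2, 0.05)
  out <- inhomogeneousSpectrum(hom, 3.35, eVert = 3.2)
  shifted <- stats::approx(grid + 0.15, intensities(hom), xout = grid,
                           yleft = 0, yright = 0)$y
  expect_equal(intensities(out), shifted, tolerance = 1e-10)
  # area preserved under convolution
  expect_equal(pracma::trapz(grid, intensities(out)), 1, tolerance = 1e-3)
})

test_that("a Gaussian ensemble convolved with a narrow line is Gaussian", {
  grid <- seq(2.0, 4.5, by = 1e-3)
  hom <- gaussianSpectrum(grid, 3.2, 0.002)
  set.seed(8)
  en <- rnorm(20000, 3.2, 0.05)
  out <- inhomogeneousSpectrum(hom, en, eVert = 3.2)
  m <- pracma::trapz(grid, grid * intensities(out)) /
       pracma::trapz(grid, intensities(out))
  v <- pracma::trapz(grid, (grid - m)^2 * intensities(out)) /
       pracma::trapz(grid, intensities(out))
  expect_lt(abs(sqrt(v) - 0.05) / 0.05, 0.02)
})

test_that("the configured mean offset moves the spectra by the shift theorem", {
  grid <- seq(2.0, 4.5, by = 1e-3)
  hom <- gaussianSpectrum(grid, 3.2, 0.03)
  set.seed(12)
  z <- rnorm(2000, 0, 0.05)
  dark <- inhomogeneousSpectrum(hom, 3.20 + z, eVert = 3.2)
  light <- inhomogeneousSpectrum(hom, 3.13 + z, eVert = 3.2)
  dPk <- firstMaximum(dark)$energy
  lPk <- firstMaximum(light)$energy
  expect_lt(abs((lPk - dPk) - (-0.07)), 1e-3 + 1e-9)
})

test_that("alignment recovers constructed shifts and preserves differences", {
  grid <- seq(2.0, 4.5, by = 1e-3)
  ref <- gaussianSpectrum(grid, 3.0, 0.05)
  # reference aligned to itself: identity
  selfAl <- alignSpectra(list(ref), ref)
  expect_equal(selfAl$shift, 0)
  expect_equal(selfAl$scale, 1)
  # displaced by +0.35 eV -> computed shift -0.35 eV
  disp <- gaussianSpectrum(grid, 3.35, 0.05)
  al <- alignSpectra(list(disp), ref)
  expect_equal(al$shift, -0.35, tolerance = 1e-9)
  # common affine map preserves dark/light peak-to-peak offsets exactly
  dark <- gaussianSpectrum(grid, 3.30, 0.05)
  light <- gaussianSpectrum(grid, 3.22, 0.05)
  al2 <- alignSpectra(list(dark = dark, light = light), ref)
  off0 <- firstMaximum(light)$energy - firstMaximum(dark)$energy
  off1 <- firstMaximum(al2$spectra$light)$energy -
          firstMaximum(al2$spectra$dark)$energy
  expect_equal(off1, off0, tolerance = 1e-12)
})

test_that("first-maximum detection requires a local maximum above threshold", {
  grid <- seq(0, 1, by = 1e-3)
  mono <- new("Spectrum", energy = grid, intensity = grid,  # monotone ramp
              normalized = FALSE, provenance = "homogeneous")
  expect_error(firstMaximum(mono), "maximum")
  # two peaks: the lowest-energy local max above 5% wins
  two <- new("Spectrum", energy = grid,
             intensity = dnorm(grid, 0.3, 0.02) + 2 * dnorm(grid, 0.7, 0.02),
             normalized = FALSE, provenance = "homogeneous")
  expect_equal(firstMaximum(two)$energy, 0.3, tolerance = 2e-3)
})
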