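test_that("vertical-gradient couplings obey the closed form and its scalings", {
  h <- genToyHessian(diatomicSpec(k = 0.5, m = c(12.011, 15.999)))
  nm <- computeModes(h$hessian, h$masses, h$geometry)

  # zero gradient -> no coupling
  vc0 <- vgCouplings(rep(0, 6), nm)
  expect_equal(hrFactors(vc0), 0)
  expect_equal(totalReorg(vc0), 0)

  # closed form S = g^2 / (2 hbar omega^3): choose the mass-weighted gradient
  # projection that makes S exactly 1, evaluated through an independent
  # SI-unit route in this test
  wn <- frequencies(nm)
  omSI <- 2 * pi * 2.99792458e10 * wn
  gUnit <- 1 / (4.359744722e-18 / (5.291772109e-11 * sqrt(1.660539067e-27)))
  gmwTarget <- sqrt(2 * 1.054571817e-34 * omSI^3) * gUnit  # Eh/(bohr sqrt(amu))
  mode <- modeVectors(nm)[, 1]
  grad <- mode * gmwTarget * rep(sqrt(h$masses), each = 3)
  vc1 <- vgCouplings(grad, nm)
  expect_equal(hrFactors(vc1), 1, tolerance = 1e-9)
  expect_equal(totalReorg(vc1), wn * physConst$eV_per_cm1, tolerance = 1e-9)

  # quadratic scaling in the gradient
  vc2 <- vgCouplings(2 * grad, nm)
  expect_equal(hrFactors(vc2), 4 * hrFactors(vc1), tolerance = 1e-12)
  expect_error(vgCouplings(rep(0, 5), nm), "3N")
})

test_that("spectral density conserves the reorganization energy", {
  # one mode, S = 1 at 1000 cm^-1: (1/pi) int J/w dw = 1000 cm^-1
  sd1 <- buildSpectralDensity(vibronicCoupling(1000, 1), width = 2,
                              kind = "gaussian")
  expect_equal(reorgFromDensity(sd1, "sticks"), 1000 * physConst$eV_per_cm1)
  expect_equal(reorgFromDensity(sd1, "grid"), 1000 * physConst$eV_per_cm1,
               tolerance = 1e-3)
  # linearity: two equal modes sum their densities
  sd2 <- buildSpectralDensity(vibronicCoupling(c(1000, 1000), c(1, 1)),
                              width = 2, kind = "gaussian")
  expect_equal(sd2@values, 2 * sd1@values[seq_along(sd2@values)],
               tolerance = 1e-10)
  # width -> 0 limit: stick reorganization unchanged by broadening bookkeeping
  sd3 <- buildSpectralDensity(vibronicCoupling(c(500, 1500), c(0.3, 0.7)),
                              width = 1e-3)
  expect_equal(reorgFromDensity(sd3, "sticks"),
               (0.3 * 500 + 0.7 * 1500) * physConst$eV_per_cm1)
  expect_error(buildSpectralDensity(vibronicCoupling(1000, 1), width = 0),
               "width")
})

test_that("reorganization energy survives random 50-mode representation changes", {
  set.seed(17)
  for (rep in 1:3) {
    wn <- runif(50, 50, 1800)
    S <- runif(50, 0.001, 0.6)
    coup <- vibronicCoupling(wn, S)
    sdn <- buildSpectralDensity(coup, width = 3, kind = "gaussian",
                                nGrid = 40000L)
    lamSticks <- sum(S * wn * physConst$eV_per_cm1)
    expect_equal(totalReorg(coup), lamSticks, tolerance = 1e-12)
    expect_equal(reorgFromDensity(sdn, "grid"), lamSticks, tolerance = 1e-4)
  }
})

test_that("single-mode T=0 lineshape matches its closed form pointwise", {
  S <- 0.8; wn <- 1200
  sdn <- buildSpectralDensity(vibronicCoupling(wn, S), width = 1)
  tg <- seq(0, 500, length.out = 2048)
  g <- lineshapeG(sdn, temperature = 0, tgrid = tg)
  w <- wavenumberToAngFreq(wn)
  gExact <- S * (1 - exp(-1i * w * tg)) - 1i * S * w * tg
  expect_lt(max(Mod(g@g - gExact)), 1e-6)
  # J = 0 -> g identically 0
  g0 <- lineshapeG(buildSpectralDensity(vibronicCoupling(1000, 0), width = 1),
                   300, tg)
  expect_equal(max(Mod(g0@g)), 0)
  expect_error(lineshapeG(sdn, 300, c(0, 1, 3)), "uniform")
})

test_that("high-temperature lineshape approaches the classical quadratic law", {
  S <- 0.5; wn <- 300
  lam <- S * wn * physConst$eV_per_cm1
  TT <- 20 * wn * physConst$eV_per_cm1 / physConst$kB_eV  # kT = 20 hbar w
  tg <- seq(0, 3, length.out = 256)                        # short times
  g <- lineshapeG(buildSpectralDensity(vibronicCoupling(wn, S), width = 1),
                  TT, tg)
  classical <- lam * physConst$kB_eV * TT * tg^2 / physConst$hbar_eV_fs^2
  i <- length(tg)
  expect_lt(abs(Re(g@g[i]) - classical[i]) / classical[i], 0.01)
})

test_that("grid quadrature of the lineshape converges on the stick answer", {
  coup <- vibronicCoupling(c(400, 1100), c(0.4, 0.3))
  tg <- seq(0, 200, length.out = 512)
  gs <- lineshapeG(buildSpectralDensity(coup, width = 1, kind = "gaussian",
                                        nGrid = 30000L), 300, tg,
                   method = "grid")
  gx <- lineshapeG(buildSpectralDensity(coup, width = 1), 300, tg)
  expect_lt(max(Mod(gs@g - gx@g)) / max(Mod(gx@g)), 0.02)
})

test_that("g = 0 yields the analytic Lorentzian of half-width gamma", {
  # long, dense time grid so the FFT energy resolution well resolves gamma
  tg <- defaultTimeGrid(nPoints = 2^17, tMax = 6e4)
  g0 <- new("Lineshape", time = tg, g = rep(0 + 0i, length(tg)),
            temperature = 300)
  gam <- 1e-3
  grid <- seq(1.0, 5.0, by = 2e-4)
  sp <- homogeneousSpectrum(g0, eVert = 3.0, grid = grid, damping = gam)
  lorentz <- (gam / pi) / ((grid - 3.0)^2 + gam^2)
  lorentz <- lorentz / pracma::trapz(grid, lorentz)
  iPk <- which.max(intensities(sp))
  expect_equal(energyGrid(sp)[iPk], 3.0, tolerance = 2e-4)
  expect_lt(max(abs(intensities(sp) - lorentz)) / max(lorentz), 0.01)
})

test_that("T=0 single-mode spectra reproduce the Franck-Condon progression", {
  wn <- 1500; hw <- wn * physConst$eV_per_cm1
  for (S in c(0.3, 1)) {
    sdn <- buildSpectralDensity(vibronicCoupling(wn, S), width = 5)
    g <- lineshapeG(sdn, temperature = 0, tgrid = defaultTimeGrid(1e-3))
    eV <- 3.0
    sp <- homogeneousSpectrum(g, eV, seq(eV - 1.2, eV + 2.4, by = 5e-4),
                              damping = 1e-3)
    E00 <- eV - S * hw
    # direct Franck-Condon summation oracle: Poisson weights over n <= 30
    for (n in 0:5) {
      w <- energyGrid(sp) >= E00 + (n - 0.5) * hw &
           energyGrid(sp) < E00 + (n + 0.5) * hw
      got <- pracma::trapz(energyGrid(sp)[w], intensities(sp)[w])
      expect_lt(abs(got - exp(-S) * S^n / factorial(n)), 0.01)
    }
  }
})

test_that("the first spectral moment equals the vertical energy", {
  set.seed(4)
  for (rep in 1:3) {
    wn <- runif(4, 300, 1700); S <- runif(4, 0.05, 0.8)
    sdn <- buildSpectralDensity(vibronicCoupling(wn, S), width = 3)
    g <- lineshapeG(sdn, 300, defaultTimeGrid(1e-3))
    eV <- 3.1
    sp <- homogeneousSpectrum(g, eV, seq(eV - 2.5, eV + 2.5, by = 1e-3))
    expect_lt(abs(spectrumMoment(sp) - eV), 1e-3)
  }
})

test_that("spectrum area is stable under grid refinement and truncation errors are raised", {
  sdn <- buildSpectralDensity(vibronicCoupling(c(700, 1400), c(0.4, 0.5)),
                              width = 3)
  g <- lineshapeG(sdn, 300, defaultTimeGrid(1e-3))
  sp1 <- homogeneousSpectrum(g, 3.0, seq(0.9, 5.1, by = 2e-3))
  sp2 <- homogeneousSpectrum(g, 3.0, seq(0.9, 5.1, by = 1e-3))
  a1 <- pracma::trapz(energyGrid(sp1), intensities(sp1))
  a2 <- pracma::trapz(energyGrid(sp2), intensities(sp2))
  expect_lt(abs(a1 - a2) / a2, 1e-4)
  expect_equal(a2, 1, tolerance = 1e-6)
  expect_error(homogeneousSpectrum(g, 3.0, seq(2.95, 3.05, by = 1e-3)),
               "truncat")
})

test_that("high-temperature spectra become Gaussian with variance 2 lambda kT", {
  S <- 5; wn <- 100
  lam <- S * wn * physConst$eV_per_cm1
  TT <- 10 * wn * physConst$eV_per_cm1 / physConst$kB_eV
  sdn <- buildSpectralDensity(vibronicCoupling(wn, S), width = 1)
  tg <- seq(0, 150, length.out = 2^14)
  g <- lineshapeG(sdn, TT, tg)
  grid <- seq(3.0 - 1.5, 3.0 + 1.5, by = 1e-3)
  sp <- homogeneousSpectrum(g, 3.0, grid, damping = 1e-4)
  m1 <- spectrumMoment(sp)
  v <- pracma::trapz(grid, (grid - m1)^2 * intensities(sp))
  expect_lt(abs(v - 2 * lam * physConst$kB_eV * TT) /
            (2 * lam * physConst$kB_eV * TT), 0.02)
})
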