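# Independent oracles and tiny molecule fixtures shared across tests.

# signed torsion via the vector-triple-product formula (independent of the
# package's atan2-of-normals implementation)
torsionOracle <- function(p1, p2, p3, p4) {
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  y <- sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  atan2(y, sum(n1 * n2)) * 180 / pi
}

diatomicSpec <- function(k = 1, m = c(1, 1), sep = 2) {
  list(positions = rbind(c(0, 0, 0), c(sep, 0, 0)), masses = m,
       bonds = data.frame(i = 1, j = 2, k = k))
}

# linear chain 1-2-3 with equal springs; 1D closed-form stretch frequencies
# for equal masses are sqrt(k/m) and sqrt(3k/m)
triatomicChain <- function(k = 1, m = 1) {
  list(positions = rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0)),
       masses = rep(m, 3),
       bonds = data.frame(i = c(1, 2), j = c(2, 3), k = c(k, k)))
}

# bent 3-atom molecule with three springs (two bonds + one closing spring so
# it has exactly 3 vibrational modes)
waterLikeSpec <- function() {
  ang <- 104.5 * pi / 180
  list(positions = rbind(c(0, 0, 0),
                         c(1.8, 0, 0),
                         1.8 * c(cos(ang), sin(ang), 0)),
       masses = c(15.999, 1.008, 1.008),
       bonds = data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                          k = c(0.5, 0.5, 0.05)))
}

randomRotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# quick Gaussian spectrum constructor for convolution tests
gaussianSpectrum <- function(grid, mean, sd, provenance = "homogeneous") {
  y <- stats::dnorm(grid, mean, sd)
  y <- y / pracma::trapz(grid, y)
  new("Spectrum", energy = grid, intensity = y, normalized = TRUE,
      provenance = provenance)
}
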