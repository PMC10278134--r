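#' @include AllClasses.R constants.R
NULL

bootMeans <- function(values, nBoot) {
  n <- length(values)
  idx <- matrix(sample.int(n, n * nBoot, replace = TRUE), nrow = nBoot)
  rowMeans(matrix(values[idx], nrow = nBoot))
}

blockBootMeans <- function(values, nBoot, blockLen) {
  n <- length(values)
  nBlocks <- ceiling(n / blockLen)
  starts <- matrix(sample.int(n - blockLen + 1L, nBlocks * nBoot,
                              replace = TRUE), nrow = nBoot)
  offs <- seq_len(blockLen) - 1L
  vapply(seq_len(nBoot), function(b) {
    ix <- as.vector(outer(offs, starts[b, ], "+"))[seq_len(n)]
    mean(values[ix])
  }, numeric(1))
}

#' Percentile bootstrap 95% confidence interval for an ensemble mean
#'
#' Frames are resampled with replacement (`nBoot` times) and the 2.5/97.5
#' percentiles of the resampled means form the interval; this treats frames as
#' i.i.d. and therefore understates uncertainty for strongly autocorrelated
#' series — a moving-block bootstrap is available via `blockLen` for such
#' cases. Deterministic for a fixed seed.
#'
#' @param values numeric series, one value per MD frame (n >= 2).
#' @param nBoot number of bootstrap resamples (>= 100; default 2000).
#' @param seed integer seed.
#' @param blockLen optional moving-block length (frames); NULL = i.i.d.
#'   bootstrap.
#' @return an [IntervalEstimate-class].
#' @export
bootstrapMeanCI <- function(values, nBoot = 2000L, seed = 1L, blockLen = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2L) stopf("need n >= 2 frames")
  if (any(!is.finite(values))) stopf("values must be finite")
  if (nBoot < 100L) stopf("nBoot must be >= 100")
  bm <- withLocalSeed(seed, {
    if (is.null(blockLen)) bootMeans(values, nBoot)
    else blockBootMeans(values, nBoot, as.integer(blockLen))
  })
  q <- stats::quantile(bm, c(0.025, 0.975), names = FALSE, type = 7)
  new("IntervalEstimate", mean = mean(values), lower = min(q[1], mean(values)),
      upper = max(q[2], mean(values)), nBoot = as.integer(nBoot),
      seed = as.integer(seed))
}

# a content-derived RNG substream per series makes the difference bootstrap
# exactly antisymmetric under argument swap
seriesSeed <- function(x, seed) {
  h <- sum(x * seq_along(x)) + 131 * length(x)
  as.integer(abs(seed * 1009 + round(h * 97)) %% 2147483587 + 1)
}

#' Bootstrap CI for a difference of two ensemble means
#'
#' Resamples each series independently and bootstraps `mean(a) - mean(b)`,
#' e.g. the light-minus-dark change of a chemical shift or band energy. Each
#' series uses its own RNG substream (derived from `seed` and the series
#' content), so swapping the arguments negates the interval exactly.
#'
#' @param a,b independent numeric series.
#' @param nBoot number of bootstrap resamples.
#' @param seed integer seed.
#' @return an [IntervalEstimate-class] for `mean(a) - mean(b)`.
#' @export
differenceCI <- function(a, b, nBoot = 2000L, seed = 1L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) stopf("need n >= 2 in both series")
  if (nBoot < 100L) stopf("nBoot must be >= 100")
  d <- withLocalSeed(seriesSeed(a, seed), bootMeans(a, nBoot)) -
       withLocalSeed(seriesSeed(b, seed), bootMeans(b, nBoot))
  q <- stats::quantile(d, c(0.025, 0.975), names = FALSE, type = 7)
  est <- mean(a) - mean(b)
  new("IntervalEstimate", mean = est, lower = min(q[1], est),
      upper = max(q[2], est), nBoot = as.integer(nBoot),
      seed = as.integer(seed))
}

#' Descriptive multimodality report for an observable distribution
#'
#' Kernel-density estimate at a stated bandwidth plus the count of local
#' density maxima; slowly exchanging conformations show up as several modes
#' in, e.g., chemical-shift distributions. Purely descriptive — no test.
#'
#' @param values numeric series (n >= 50).
#' @param bandwidth KDE bandwidth in observable units; default
#'   `stats::bw.nrd0`.
#' @param nBins histogram bin count for the returned counts.
#' @return list with `nModes`, `modes` (locations), `density` (the
#'   [stats::density()] object) and `histogram` ([graphics::hist()] data).
#' @export
multimodalityReport <- function(values, bandwidth = NULL, nBins = 30L) {
  values <- as.numeric(values)
  if (length(values) < 50L) stopf("need n >= 50 for a density report")
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(values)
  den <- stats::density(values, bw = bandwidth)
  y <- den$y
  n <- length(y)
  isMax <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                    y[2:(n - 1)] >= y[3:n], FALSE) &
           y > 0.01 * max(y)
  h <- graphics::hist(values, breaks = nBins, plot = FALSE)
  list(nModes = sum(isMax), modes = den$x[isMax], density = den,
       histogram = h)
}
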