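#' Theoretical autocovariance of fractional Gaussian noise
#'
#' For unit-variance fGn with Hurst exponent H,
#' gamma(k) = (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}) / 2.
#' At lag 1 this reduces to 2^{2H-1} - 1 (zero for H = 0.5, white noise).
#'
#' @param k integer lag(s).
#' @param hurst Hurst exponent in (0, 1).
#' @return autocovariance value(s).
#' @export
fgnAutocovariance <- function(k, hurst) {
  stopifnot(hurst > 0, hurst < 1)
  0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
           abs(k - 1)^(2 * hurst))
}

#' Simulate fractional Gaussian noise by circulant embedding
#'
#' Exact-covariance synthesis (Davies–Harte): the target autocovariance
#' sequence is embedded in a circulant matrix whose eigenvalues are obtained
#' by FFT; a complex Gaussian vector coloured by the square-root eigenvalues
#' transforms back to a Gaussian series with exactly the fGn autocovariance.
#' The sample lag-1 autocorrelation therefore converges to
#' `fgnAutocovariance(1, hurst)` as `n` grows.
#'
#' @param n number of samples (>= 2).
#' @param hurst Hurst exponent, strictly in (0, 1).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return numeric vector of length `n`, unit variance in expectation.
#' @examples
#' x <- fgnSim(1024, 0.8, seed = 1)
#' acf(x, lag.max = 1, plot = FALSE)$acf[2]  # near 2^0.6/2 - 1 = 0.516
#' @export
fgnSim <- function(n, hurst, seed = NULL) {
  if (!is.numeric(hurst) || length(hurst) != 1L || hurst <= 0 || hurst >= 1)
    stop("hurst must lie strictly in (0, 1)")
  if (n < 2) stop("n must be at least 2")
  n <- as.integer(n)
  withSeed(seed, {
    g <- fgnAutocovariance(0:n, hurst)
    lam <- Re(stats::fft(c(g, g[n:2])))  # circulant eigenvalues, length 2n
    if (min(lam) < -1e-8 * max(lam))
      stop("circulant embedding is not positive semi-definite (min eigenvalue ",
           format(min(lam)), "); internal error")
    lam[lam < 0] <- 0
    m <- 2L * n
    a <- complex(length.out = m)
    a[1L] <- sqrt(lam[1L]) * stats::rnorm(1)
    a[n + 1L] <- sqrt(lam[n + 1L]) * stats::rnorm(1)
    idx <- 2:n
    a[idx] <- sqrt(lam[idx] / 2) *
      complex(real = stats::rnorm(n - 1), imaginary = stats::rnorm(n - 1))
    a[m + 2L - idx] <- Conj(a[idx])
    Re(stats::fft(a))[1:n] / sqrt(m)
  })
}

#' Simulate fractional Brownian motion
#'
#' Cumulative sum of [fgnSim()] output: an fBm track with the same Hurst
#' exponent. fBm is the self-affine process for which the fractal-dimension
#' relation FD = 2 - H holds, so these tracks are the ground truth for
#' [higuchiFD()] validation, while the fGn increments are the ground truth
#' for [hurstRS()].
#'
#' @inheritParams fgnSim
#' @return numeric vector of length `n`.
#' @export
fbmSim <- function(n, hurst, seed = NULL) {
  cumsum(fgnSim(n, hurst, seed))
}
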