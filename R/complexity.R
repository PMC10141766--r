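# Nonlinear complexity features: Higuchi fractal dimension and
# rescaled-range (R/S) Hurst exponent.

#' Higuchi fractal dimension
#'
#' For each interval `k = 1..kmax` and offset `m = 1..k` the sub-series
#' `x[m], x[m+k], x[m+2k], ...` yields a curve length
#' `L_m(k) = (sum |x[m+ik] - x[m+(i-1)k]|) * (N-1) / (floor((N-m)/k) * k) / k`
#' (the `(N-1)/(floor((N-m)/k) k)` term is the normalization factor);
#' lengths are averaged over `m` to `L(k)`, and the fractal dimension is the
#' least-squares slope of `ln L(k)` against `ln(1/k)`. For a self-affine
#' track the result lies in \[1, 2\]: 1 for a straight line, 2 for a
#' plane-filling white-noise path, and `2 - H` for fractional Brownian
#' motion with Hurst exponent H.
#'
#' Estimates outside \[1, 2\] (possible on short, non-fractal windows) are
#' returned as computed with a warning, never silently clipped.
#'
#' @param x numeric window (finite values).
#' @param kmax maximum interval, `2 <= kmax < length(x)/2` (default 20, the
#'   saturation point of the estimate on 1500-sample EEG windows).
#' @return estimated fractal dimension.
#' @examples
#' higuchiFD(seq_len(1500))            # exactly 1 for a line
#' higuchiFD(fbmSim(1500, 0.5, seed = 1))  # near 1.5
#' @export
higuchiFD <- function(x, kmax = 20) {
  N <- length(x)
  if (!all(is.finite(x))) stop("window contains non-finite values")
  if (kmax < 2 || kmax >= N / 2) stop("kmax must satisfy 2 <= kmax < N/2")
  Lk <- numeric(kmax)
  for (k in seq_len(kmax)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      nk <- (N - m) %/% k
      idx <- m + (0:nk) * k
      Lm[m] <- sum(abs(diff(x[idx]))) * (N - 1) / (nk * k) / k
    }
    Lk[k] <- mean(Lm)
  }
  if (any(Lk == 0))
    stop("degenerate signal: zero curve length (constant window)")
  lk <- log(Lk)
  li <- log(1 / seq_len(kmax))
  fd <- sum((li - mean(li)) * (lk - mean(lk))) / sum((li - mean(li))^2)
  if (fd < 1 - 1e-9 || fd > 2 + 1e-9)
    warning(sprintf("Higuchi FD %.4f outside [1, 2]; window may not be fractal", fd))
  fd
}

#' Rescaled-range (R/S) Hurst exponent
#'
#' For each block length `n` on a dyadic grid from `minSubset` to `N/2` the
#' window is split into `m = floor(N/n)` adjacent subsets (remainder samples
#' discarded); each subset is demeaned, cumulated, and scored by its range
#' `R = max - min` of the cumulative deviations rescaled by its standard
#' deviation `S`; the `R/S` values are averaged per block length, and the
#' Hurst exponent is the least-squares slope of `log(R/S)` against
#' `log(n)`. H = 0.5 indicates an uncorrelated series, H > 0.5 persistent
#' long memory.
#'
#' `useLogReturns = TRUE` first transforms the series to logarithmic returns
#' `log(x[i+1]/x[i])` (meaningful for strictly positive series only, e.g.
#' prices; band-passed EEG crosses zero, so the default is FALSE).
#'
#' @param x numeric window.
#' @param minSubset smallest block length (>= 8; default 64 — shorter
#'   blocks carry the well-known small-sample upward bias of R/S).
#' @param useLogReturns transform to log-returns first (default FALSE).
#' @return estimated Hurst exponent.
#' @examples
#' hurstRS(fgnSim(1500, 0.8, seed = 1))  # near 0.8
#' @export
hurstRS <- function(x, minSubset = 64, useLogReturns = FALSE) {
  if (minSubset < 8) stop("minSubset must be at least 8")
  if (useLogReturns) {
    if (any(x <= 0))
      stop("log-returns require a strictly positive series")
    x <- diff(log(x))
  }
  N <- length(x)
  if (N < 4 * minSubset)
    stop("window must be at least 4 * minSubset samples long")
  ns <- 2^(seq.int(floor(log2(minSubset)), floor(log2(N / 2))))
  rs <- rep(NA_real_, length(ns))
  for (u in seq_along(ns)) {
    n <- ns[u]
    m <- N %/% n
    vals <- numeric(0)
    for (j in seq_len(m)) {
      seg <- x[((j - 1) * n + 1):(j * n)]
      dev <- seg - mean(seg)
      S <- sqrt(mean(dev^2))
      if (S == 0) next  # flat subset excluded
      cums <- cumsum(dev)
      vals <- c(vals, (max(cums) - min(cums)) / S)
    }
    if (length(vals) < m)
      warning("excluded ", m - length(vals),
              " zero-variance subset(s) at block length ", n)
    if (length(vals)) rs[u] <- mean(vals)
  }
  ok <- is.finite(rs)
  if (sum(ok) < 2)
    stop("degenerate signal: too few usable block lengths for the R/S slope")
  ln <- log(ns[ok]); lr <- log(rs[ok])
  sum((ln - mean(ln)) * (lr - mean(lr))) / sum((ln - mean(ln))^2)
}

#' Expected rescaled range from the scaling law
#'
#' Evaluates `(2^(2H-1) - 1) * n^H`, a formula sometimes quoted alongside
#' R/S analysis. Note that its first factor is the lag-1 autocovariance of
#' fractional Gaussian noise (zero at H = 0.5!), not the R/S prefactor, so
#' the expression is inconsistent with the scaling law `E[R/S] ~ c * n^H`
#' whose log-log slope [hurstRS()] estimates; it is provided for reference
#' only and is used nowhere in the pipeline.
#'
#' @param n block length.
#' @param hurst Hurst exponent.
#' @return the quoted quantity.
#' @export
rescaledRangeFormula <- function(n, hurst) {
  (2^(2 * hurst - 1) - 1) * n^hurst
}
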