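# Irregularity features: Tsallis entropy (generic q-form and Sneddon
# critical-point approximation) and dispersion entropy.

#' Tsallis entropy of a probability vector
#'
#' `S_T = (1 - sum(p_i^q)) / (q - 1)` for non-extensivity parameter
#' `q != 1`; the `q -> 1` limit is the Shannon entropy (natural log), and
#' `q = 1` dispatches to it rather than dividing by zero.
#'
#' @param p probability vector (non-negative, sums to 1 within 1e-9).
#' @param q non-extensivity parameter (> 0), default 2.
#' @return entropy value.
#' @examples
#' tsallisQ(rep(0.25, 4), q = 2)  # 0.75
#' @export
tsallisQ <- function(p, q = 2) {
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1")
  if (q <= 0) stop("q must be positive")
  if (q == 1) {
    pp <- p[p > 0]
    return(-sum(pp * log(pp)))
  }
  (1 - sum(p^q)) / (q - 1)
}

#' Tsallis entropy via Sneddon's critical-point approximation
#'
#' Approximates the q = 2 Tsallis entropy of a signal from its local
#' critical points: positions where the discrete derivative is zero or
#' changes sign partition the window into `N` bins, and
#' `S_T ~= 1 - (1/N) * sum(s_i^2 / sigma^2)` with `s_i^2` the variance
#' inside bin i and `sigma^2` the whole-window variance (population
#' variances). The value is at most 1: 1 when every bin is internally
#' constant, 0 when every bin is as variable as the whole window.
#'
#' @param x numeric window with at least 3 samples and nonzero variance.
#' @return entropy value (<= 1).
#' @export
tsallisSneddon <- function(x) {
  n <- length(x)
  if (n < 3) stop("window must have at least 3 samples")
  sigma2 <- mean((x - mean(x))^2)
  if (sigma2 == 0) stop("degenerate signal: zero variance")
  d <- diff(x)
  s <- sign(d)
  # critical points: zero derivative (bin closes after the flat pair) or a
  # sign flip relative to the previous nonzero derivative (bin closes at the
  # extremum sample)
  crit <- integer(0)
  lastSign <- 0
  for (i in seq_along(s)) {
    if (s[i] == 0) crit <- c(crit, i + 1L)
    else {
      if (lastSign != 0 && s[i] != lastSign) crit <- c(crit, i)
      lastSign <- s[i]
    }
  }
  bounds <- sort(unique(c(0L, crit[crit < n], n)))
  nb <- length(bounds) - 1L
  if (nb < 2) {
    warning("fewer than 2 critical points; single-bin Sneddon estimate")
  }
  sratio <- vapply(seq_len(nb), function(b) {
    seg <- x[(bounds[b] + 1):bounds[b + 1]]
    mean((seg - mean(seg))^2) / sigma2
  }, 0)
  1 - mean(sratio)
}

#' Histogram-based Tsallis entropy of a signal
#'
#' Alternative to [tsallisSneddon()]: the signal's amplitude distribution is
#' binned into `nBins` equal-width bins and [tsallisQ()] is applied to the
#' bin probabilities. Unlike the Sneddon approximation this is not bounded
#' by 1 for q near 1.
#'
#' @param x numeric window.
#' @param q non-extensivity parameter.
#' @param nBins histogram bin count (>= 2).
#' @return entropy value.
#' @export
tsallisHistogram <- function(x, q = 2, nBins = 16) {
  if (nBins < 2) stop("nBins must be at least 2")
  if (max(x) == min(x)) stop("degenerate signal: zero variance")
  h <- tabulate(cut(x, breaks = nBins, labels = FALSE), nbins = nBins)
  tsallisQ(h / sum(h), q)
}

# Map a signal into integer classes 1..c through the normal CDF of the
# standardized signal.
ncdfMap <- function(x, c) {
  mu <- mean(x); sdev <- stats::sd(x)
  if (sdev == 0) return(rep(1L, length(x)))
  y <- stats::pnorm(x, mu, sdev)
  u <- as.integer(round(c * y + 0.5))
  pmin(pmax(u, 1L), as.integer(c))
}

#' Dispersion entropy
#'
#' The signal is mapped to integer classes `1..c` (default: normal-CDF of
#' the standardized signal, then `round(c*y + 0.5)`); overlapping embedded
#' vectors of length `m` at delay `d` form dispersion patterns, whose
#' relative frequencies (denominator `N - (m-1)*d`) enter Shannon's entropy
#' `-sum(p * ln p)`. The result lies in `[0, ln(c^m)]`: 0 for a strictly
#' repeating single pattern, `ln(c^m)` when all `c^m` patterns are
#' equiprobable. The mapping normalizes by the signal's own distribution,
#' so the value is invariant to positive affine transforms of the input.
#'
#' @param x numeric window, `length(x) > (m-1)*d + 1` and `c^m <
#'   length(x)`.
#' @param m embedding dimension (>= 2), default 2.
#' @param c number of classes (> 1), default 2.
#' @param d time delay, default 1 (the recommended value).
#' @param mapping `"ncdf"` (default) or `"none"` (input already holds
#'   integer classes `1..c`).
#' @return entropy in nats.
#' @examples
#' dispersionEntropy(c(1, 2, 1, 2, 1), mapping = "none")  # ln 2
#' @export
dispersionEntropy <- function(x, m = 2, c = 2, d = 1,
                              mapping = c("ncdf", "none")) {
  mapping <- match.arg(mapping)
  if (c <= 1) stop("c must exceed 1")
  if (m < 2) stop("m must be at least 2")
  N <- length(x)
  if (c^m >= N)
    stop("c^m must be smaller than the series length")
  if (N <= (m - 1) * d + 1) stop("series too short for the embedding")
  if (mapping == "ncdf") {
    if (stats::sd(x) == 0) {
      warning("constant signal: degenerate mapping, entropy 0")
      return(0)
    }
    u <- ncdfMap(x, c)
  } else {
    u <- as.integer(x)
    if (any(u < 1 | u > c)) stop("classified input must lie in 1..c")
  }
  nPat <- N - (m - 1) * d
  # encode each pattern as an integer in base c
  code <- integer(nPat)
  for (j in seq_len(m) - 1L)
    code <- code * c + (u[(1 + j * d):(nPat + j * d)] - 1L)
  p <- tabulate(code + 1L, nbins = c^m)
  p <- p[p > 0] / nPat
  -sum(p * log(p))
}
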