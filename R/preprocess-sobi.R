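# SOBI blind source separation: whitening followed by joint approximate
# diagonalization of time-lagged covariance matrices (Jacobi rotations with
# the closed-form Givens angle of Cardoso & Souloumiac).

jointDiagonalize <- function(Ms, tol = 1e-9, maxSweeps = 200) {
  p <- dim(Ms)[1]
  K <- dim(Ms)[3]
  V <- diag(p)
  for (sweep in seq_len(maxSweeps)) {
    changed <- FALSE
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      h1 <- Ms[i, i, ] - Ms[j, j, ]
      h2 <- Ms[i, j, ] + Ms[j, i, ]
      G <- matrix(c(sum(h1 * h1), sum(h1 * h2),
                    sum(h1 * h2), sum(h2 * h2)), 2)
      ev <- eigen(G, symmetric = TRUE)$vectors[, 1]
      if (ev[1] < 0) ev <- -ev
      c0 <- sqrt((ev[1] + 1) / 2)
      s0 <- ev[2] / (2 * c0)
      if (abs(s0) > tol) {
        changed <- TRUE
        # rotate rows/columns i and j of every target matrix
        Mi <- Ms[i, , ]; Mj <- Ms[j, , ]
        Ms[i, , ] <- c0 * Mi + s0 * Mj
        Ms[j, , ] <- -s0 * Mi + c0 * Mj
        Mi <- Ms[, i, ]; Mj <- Ms[, j, ]
        Ms[, i, ] <- c0 * Mi + s0 * Mj
        Ms[, j, ] <- -s0 * Mi + c0 * Mj
        Vi <- V[, i]
        V[, i] <- c0 * Vi + s0 * V[, j]
        V[, j] <- -s0 * Vi + c0 * V[, j]
      }
    }
    if (!changed) break
  }
  V
}

#' Second-order blind identification (SOBI)
#'
#' Estimates an unmixing of the EEG channels by (1) removing channel means,
#' (2) whitening via the zero-lag covariance, and (3) jointly
#' approximately diagonalizing the symmetrized time-lagged covariance
#' matrices at lags `1..nLags`. Sources with distinct autocorrelation
#' structure (coloured sources) are identifiable up to permutation and
#' scale; for temporally white sources the lagged covariances carry no
#' information and the result is flagged low-confidence.
#'
#' @param rec a [RawRecording-class] (EEG channels only enter the
#'   decomposition; EOG channels are held out as artifact references) or a
#'   channels x samples numeric matrix.
#' @param nLags number of covariance lags (default 100, i.e. up to 400 ms
#'   at 250 Hz).
#' @return an [ICDecomposition-class] with as many components as EEG
#'   channels (fewer, with a warning, when the channel covariance is
#'   rank-deficient).
#' @export
sobi <- function(rec, nLags = 100) {
  if (is(rec, "RawRecording")) {
    X <- rec@data[rec@channelRoles == "EEG", , drop = FALSE]
    labels <- rec@channelLabels[rec@channelRoles == "EEG"]
  } else {
    X <- as.matrix(rec)
    labels <- rownames(X)
    if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(X)))
  }
  p <- nrow(X); n <- ncol(X)
  if (n <= 10 * p) stop("SOBI needs many more samples than channels")
  center <- rowMeans(X)
  X <- X - center

  C0 <- tcrossprod(X) / n
  e <- eigen(C0, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-10
  if (!all(keep)) {
    warning("rank-deficient channel covariance: reducing to ",
            sum(keep), " components")
  }
  d <- e$values[keep]
  U <- e$vectors[, keep, drop = FALSE]
  whitener <- diag(1 / sqrt(d), nrow = length(d)) %*% t(U)
  Z <- whitener %*% X

  q <- nrow(Z)
  lags <- seq_len(nLags)
  Ms <- array(0, c(q, q, nLags))
  lagStrength <- numeric(nLags)
  for (k in lags) {
    M <- tcrossprod(Z[, 1:(n - k), drop = FALSE],
                    Z[, (k + 1):n, drop = FALSE]) / (n - k)
    M <- (M + t(M)) / 2
    Ms[, , k] <- M
    lagStrength[k] <- sqrt(mean(M^2))
  }
  lowConf <- mean(lagStrength) < 2 / sqrt(n)
  if (lowConf)
    warning("lagged covariances are near zero (temporally white sources); ",
            "SOBI separation is low-confidence")

  V <- jointDiagonalize(Ms)
  W <- t(V) %*% whitener                       # components x channels
  A <- U %*% diag(sqrt(d), nrow = length(d)) %*% V  # channels x components
  new("ICDecomposition",
      mixing = A, unmixing = W, sources = W %*% X,
      xcorrScores = matrix(numeric(), 0, 0),
      artifactFlags = logical(q),
      channelLabels = labels, center = center,
      lowConfidence = lowConf)
}

#' Amari index of a separation product
#'
#' Permutation- and scale-invariant distance of `P = unmixing %*% mixing`
#' from a scaled permutation matrix; 0 means perfect source recovery. The
#' standard figure of merit for blind source separation.
#'
#' @param P square matrix (estimated unmixing times true mixing).
#' @return non-negative scalar; values below 0.1 indicate good recovery.
#' @export
amariIndex <- function(P) {
  P <- abs(as.matrix(P))
  p <- nrow(P)
  stopifnot(p == ncol(P))
  rowPart <- sum(P / apply(P, 1, max)) - p
  colPart <- sum(t(t(P) / apply(P, 2, max))) - p
  (rowPart + colPart) / (2 * p * (p - 1))
}
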