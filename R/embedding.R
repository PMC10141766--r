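# Laplacian Eigenmap: kNN similarity graph, generalized eigenproblem
# L y = lambda D y, and Nystrom-style out-of-sample extension.

#' Standardize feature columns
#'
#' Zero mean, unit variance per column; constant columns are left centered.
#' Returns the standardized matrix with the centers/scales attached so test
#' data can be standardized with training statistics.
#'
#' @param x numeric matrix.
#' @param center,scale optional precomputed statistics (training-fold
#'   values).
#' @return matrix with attributes `center` and `scale`.
#' @export
standardizeFeatures <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0] <- 1
  }
  out <- sweep(sweep(x, 2, center), 2, scale, `/`)
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Build a symmetrized k-nearest-neighbour graph
#'
#' Edge i–j is present iff j is among i's k nearest Euclidean neighbours or
#' vice versa (OR symmetrization). Weights are 1 (`binary`) or
#' `exp(-||x_i - x_j||^2 / t)` (`heat`). Features should be standardized
#' first ([standardizeFeatures()]) so no column dominates the distances.
#'
#' @param features trials x features numeric matrix.
#' @param nNeighbors k, below the trial count.
#' @param scheme `"binary"` (default) or `"heat"`.
#' @param heatT heat-kernel bandwidth t (default: median squared neighbour
#'   distance).
#' @return a [NeighborGraph-class].
#' @export
buildNeighborGraph <- function(features, nNeighbors = 5,
                               scheme = c("binary", "heat"), heatT = NULL) {
  scheme <- match.arg(scheme)
  X <- as.matrix(features)
  n <- nrow(X)
  if (nNeighbors >= n) stop("nNeighbors must be below the trial count")
  D2 <- as.matrix(stats::dist(X))^2
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(D2[i, ])[2:(nNeighbors + 1)]  # skip self
    W[i, nb] <- 1
  }
  W <- pmax(W, t(W))                       # OR-rule symmetrization
  if (scheme == "heat") {
    if (is.null(heatT)) heatT <- stats::median(D2[W > 0])
    W <- W * exp(-D2 / heatT)
  } else heatT <- NA_real_
  diag(W) <- 0
  new("NeighborGraph", weights = W, degree = rowSums(W),
      nNeighbors = as.integer(nNeighbors), features = X,
      scheme = scheme, heatT = heatT)
}

#' Laplacian Eigenmap embedding
#'
#' Solves the generalized eigenproblem `L y = lambda D y` with
#' `L = D - W` via the symmetric form `D^{-1/2} L D^{-1/2}`: eigenvalues
#' are non-negative with one zero per connected component (constant
#' eigenvector on the component). The trivial constant eigenvector is
#' discarded and the next `r` eigenvectors, rescaled by `D^{-1/2}`, become
#' the coordinates, which satisfy the constraint `Y' D Y = I` and minimize
#' `tr(Y' L Y) = sum of the retained eigenvalues`. On a disconnected graph
#' (warned, or an error under `strict`) the remaining zero-eigenvalue
#' eigenvectors encode component membership and are retained.
#'
#' @param g a [NeighborGraph-class].
#' @param r embedding dimension, below the usable spectrum size.
#' @param strict error (rather than warn) on a disconnected graph.
#' @return an [EmbeddingResult-class].
#' @export
laplacianEmbed <- function(g, r = 10, strict = FALSE) {
  stopifnot(is(g, "NeighborGraph"))
  W <- g@weights
  n <- nrow(W)
  if (r >= n) stop("r must be below the trial count")
  deg <- rowSums(W)
  if (any(deg <= 0)) stop("graph has isolated vertices (zero degree)")
  dHalf <- 1 / sqrt(deg)
  Lsym <- -W * outer(dHalf, dHalf)
  diag(Lsym) <- diag(Lsym) + 1   # D^{-1/2} (D - W) D^{-1/2}
  e <- eigen(Lsym, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, rev(seq_len(n)), drop = FALSE]
  vals[vals < 0 & vals > -1e-10] <- pmax(vals[vals < 0 & vals > -1e-10], 0)

  tol <- 1e-8
  nComp <- sum(vals < tol)
  if (nComp > 1) {
    msg <- paste0("graph is disconnected (", nComp, " components)")
    if (strict) stop(msg)
    warning(msg, "; embedding spans all components")
    # the zero eigenvalue is degenerate and eigen() returns an arbitrary
    # basis of its subspace; rotate it so the first basis vector is the
    # global constant direction (D^{1/2} 1 in the symmetric coordinates)
    # and the retained vectors are honest component indicators
    zi <- seq_len(nComp)
    u0 <- sqrt(deg) / sqrt(sum(deg))
    Q <- qr.Q(qr(cbind(u0, vecs[, zi, drop = FALSE])))[, zi, drop = FALSE]
    vecs[, zi] <- Q
  }
  # drop exactly one trivial eigenvector; on a disconnected graph the
  # remaining zero-eigenvalue eigenvectors encode component membership and
  # are kept as coordinates
  keep <- 2:min(1 + r, n)
  if (length(keep) < r)
    warning("spectrum exhausted: returning ", length(keep), " dimensions")
  Y <- vecs[, keep, drop = FALSE] * dHalf
  new("EmbeddingResult",
      eigenvalues = vals[keep], coordinates = Y,
      r = as.integer(length(keep)), allEigenvalues = vals,
      nComponents = as.integer(nComp), degree = deg)
}

#' Nystrom-style out-of-sample extension
#'
#' Maps new trials into an existing embedding without refitting: each test
#' point's coordinate is the weighted average of the coordinates of its k
#' nearest training points, with weights from the graph's scheme (uniform
#' for binary, heat-kernel otherwise). This is how test folds are embedded
#' during cross-validation so the eigenproblem never sees them.
#'
#' @param g the training [NeighborGraph-class].
#' @param emb the training [EmbeddingResult-class].
#' @param newFeatures new trials x features matrix, standardized with the
#'   training statistics.
#' @return new-trials x r coordinate matrix.
#' @export
nystromExtend <- function(g, emb, newFeatures) {
  X <- g@features
  Xn <- as.matrix(newFeatures)
  k <- g@nNeighbors
  out <- matrix(0, nrow(Xn), ncol(emb@coordinates))
  for (i in seq_len(nrow(Xn))) {
    d2 <- colSums((t(X) - Xn[i, ])^2)
    nb <- order(d2)[seq_len(k)]
    w <- if (g@scheme == "heat") exp(-d2[nb] / g@heatT) else rep(1, k)
    out[i, ] <- colSums(emb@coordinates[nb, , drop = FALSE] * w) / sum(w)
  }
  out
}
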