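# Neighbour graph construction and Laplacian Eigenmap spectral properties.

test_that("kNN graph symmetrization follows the OR rule", {
  # three collinear equidistant points, k = 1: the middle point is the
  # nearest neighbour of both ends, so symmetrization connects it to both
  X <- matrix(c(0, 1, 2), ncol = 1)
  g <- buildNeighborGraph(X, 1)
  W <- g@weights
  expect_equal(W[2, 1], 1)
  expect_equal(W[2, 3], 1)
  expect_equal(diag(W), rep(0, 3))
  expect_equal(W, t(W))
})

test_that("far-separated clusters give a block-diagonal graph", {
  set.seed(81)
  X <- rbind(matrix(rnorm(30, sd = 0.1), 10), matrix(rnorm(30, sd = 0.1) + 50, 10))
  g <- buildNeighborGraph(X, 3)
  expect_equal(max(g@weights[1:10, 11:20]), 0)
  expect_gt(min(rowSums(g@weights)), 0)
})

test_that("k = n - 1 yields the complete graph and k >= n errors", {
  set.seed(82)
  X <- matrix(rnorm(8 * 3), 8)
  g <- buildNeighborGraph(X, 7)
  expect_true(all(g@weights[upper.tri(g@weights)] > 0))
  expect_error(buildNeighborGraph(X, 8), "below the trial count")
})

test_that("heat-kernel weights decay with distance", {
  X <- matrix(c(0, 1, 3), ncol = 1)
  g <- buildNeighborGraph(X, 2, scheme = "heat", heatT = 4)
  expect_equal(g@weights[1, 2], exp(-1 / 4))
  expect_equal(g@weights[2, 3], exp(-4 / 4))
  expect_gt(g@weights[1, 2], g@weights[1, 3])
})

test_that("the Laplacian spectrum has one zero per connected component", {
  set.seed(83)
  X <- matrix(rnorm(60), 20)
  g <- buildNeighborGraph(X, 4)
  emb <- laplacianEmbed(g, 3)
  expect_equal(emb@nComponents, 1L)
  expect_lt(min(emb@allEigenvalues), 1e-10)
  # the discarded trivial eigenvector is constant: check directly
  deg <- g@degree
  L <- diag(deg) - g@weights
  expect_lt(max(abs(L %*% rep(1, 20))), 1e-10)

  # two components -> exactly two near-zero eigenvalues
  X2 <- rbind(matrix(rnorm(30, sd = 0.1), 10),
              matrix(rnorm(30, sd = 0.1) + 50, 10))
  g2 <- buildNeighborGraph(X2, 3)
  expect_warning(emb2 <- laplacianEmbed(g2, 2), "disconnected")
  expect_equal(emb2@nComponents, 2L)
  expect_equal(sum(emb2@allEigenvalues < 1e-8), 2)
  expect_error(laplacianEmbed(g2, 2, strict = TRUE), "disconnected")
})

test_that("coordinates satisfy the generalized orthogonality constraint", {
  set.seed(84)
  X <- matrix(rnorm(120), 30)
  g <- buildNeighborGraph(X, 5)
  emb <- laplacianEmbed(g, 6)
  Y <- coordinates(emb)
  D <- diag(emb@degree)
  expect_lt(max(abs(t(Y) %*% D %*% Y - diag(6))), 1e-6)
  # objective consistency: tr(Y' L Y) equals the retained eigenvalue sum
  L <- D - g@weights
  expect_equal(sum(diag(t(Y) %*% L %*% Y)), sum(eigenvalues(emb)),
               tolerance = 1e-8)
})

test_that("permuting trials permutes coordinates identically", {
  set.seed(85)
  X <- matrix(rnorm(90), 30)
  perm <- sample(30)
  g1 <- laplacianEmbed(buildNeighborGraph(X, 5), 2)
  g2 <- laplacianEmbed(buildNeighborGraph(X[perm, ], 5), 2)
  # eigenvectors are sign-ambiguous; align columns before comparing
  for (j in 1:2) {
    a <- coordinates(g1)[perm, j]; b <- coordinates(g2)[, j]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  }
})

test_that("the first nontrivial coordinate bisects two Gaussian clusters", {
  agree <- vapply(1:20, function(s) {
    X <- twoClusters(seed = 900 + s)
    g <- buildNeighborGraph(X, 5)
    emb <- suppressWarnings(laplacianEmbed(g, 1))
    lab <- rep(c(FALSE, TRUE), each = 20)
    a <- mean((coordinates(emb)[, 1] > 0) == lab)
    max(a, 1 - a)
  }, 0)
  expect_gte(mean(agree), 0.95)
})

test_that("embedding preserves input-space neighbourhoods better than a random projection", {
  set.seed(86)
  Xs <- rbind(matrix(rnorm(150), 30), matrix(rnorm(150) + 2, 30))
  g <- buildNeighborGraph(Xs, 5)
  emb <- suppressWarnings(laplacianEmbed(g, 2))
  nnOverlap <- function(A, B, k = 5) {
    da <- as.matrix(dist(A)); db <- as.matrix(dist(B))
    mean(vapply(seq_len(nrow(A)), function(i) {
      na <- order(da[i, ])[2:(k + 1)]
      nb <- order(db[i, ])[2:(k + 1)]
      length(intersect(na, nb)) / k
    }, 0))
  }
  proj <- Xs %*% matrix(rnorm(ncol(Xs) * 2), ncol = 2) / sqrt(2)
  expect_gt(nnOverlap(Xs, coordinates(emb)), nnOverlap(Xs, proj))
})

test_that("Nystrom extension places held-out points near their neighbours", {
  set.seed(87)
  X <- twoClusters(seed = 88, n = 25)
  tr <- c(1:20, 26:45); te <- setdiff(1:50, tr)
  Xtr <- X[tr, ]; Xte <- X[te, ]
  g <- buildNeighborGraph(Xtr, 5)
  emb <- suppressWarnings(laplacianEmbed(g, 1))
  Yte <- nystromExtend(g, emb, Xte)
  lab <- rep(c(FALSE, TRUE), each = 5)
  a <- mean((Yte[, 1] > 0) == lab)
  expect_gte(max(a, 1 - a), 0.9)
})
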