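test_that("inertia matches its weighted double-sum form", {
  blocks <- small_feature_blocks()
  Z <- blocks[[1]]
  expect_equal(inertia(Z), nrow(Z), tolerance = 1e-8)
  expect_equal(inertia(matrix(0, 4, 6)), 0)

  set.seed(14)
  X <- matrix(rnorm(40), 5, 8)
  X <- X - rowMeans(X)
  w <- runif(8); w <- w / sum(w)
  A <- matrix(rnorm(25), 5); Q <- crossprod(A) + diag(5)
  direct <- 0
  for (i in 1:8) direct <- direct + w[i] * drop(t(X[, i]) %*% Q %*% X[, i])
  expect_equal(inertia(X, w, Q), direct, tolerance = 1e-10)
  expect_error(inertia(X, w[1:3]), "length")
})

test_that("coinertia equals the trace and double-sum forms", {
  set.seed(15)
  X <- matrix(rnorm(12), 3, 4); X <- X - rowMeans(X)
  Y <- matrix(rnorm(8), 2, 4); Y <- Y - rowMeans(Y)
  n <- 4; w <- rep(1 / n, n)
  got <- coinertia(X, Y)
  # trace form via explicit matrix products (samples-as-rows orientation)
  W <- diag(w)
  tr <- sum(diag(t(X) %*% X %*% W %*% t(Y) %*% Y %*% W))
  expect_equal(got, tr, tolerance = 1e-10)
  # sum over any complete orthonormal bases of squared projected covariances
  # equals ||X W Y'||_F^2
  frob <- sum((X %*% W %*% t(Y))^2)
  expect_equal(got, frob, tolerance = 1e-10)
  # eigenbasis double-sum (the decomposition the trace identity comes from)
  U <- eigen(X %*% W %*% t(X))$vectors
  V <- eigen(Y %*% W %*% t(Y))$vectors
  dbl <- 0
  for (k in 1:3) for (j in 1:2)
    dbl <- dbl + drop(t(U[, k]) %*% X %*% W %*% t(Y) %*% V[, j])^2
  expect_equal(got, dbl, tolerance = 1e-10)

  expect_gte(coinertia(X, X), 0)
  expect_equal(coinertia(X, X), sum(diag((t(X) %*% X %*% W) %*%
                                           (t(X) %*% X %*% W))),
               tolerance = 1e-10)
  # W-orthogonal blocks have zero co-inertia
  Y0 <- matrix(c(1, -1, 1, -1), 1)
  X0 <- matrix(c(1, 1, -1, -1), 1)
  expect_lt(abs(coinertia(X0, Y0)), 1e-10)
  expect_error(coinertia(X, Y[, 1:3]), "same number")
})

test_that("MCIA axis 1 is optimal against random feasible directions", {
  blocks <- small_feature_blocks(n = 10, dims = c(14, 11))
  fit <- mcia_fit(blocks, n_axes = 1, block_scaling = "none")
  n <- 10; w <- rep(1 / n, n)
  objective <- function(us, h) {
    sum(vapply(seq_along(blocks), function(s)
      sum(us[[s]] * (unclass(blocks[[s]]) %*% (w * h)))^2, numeric(1)))
  }
  set.seed(99)
  best_random <- 0
  for (r in 1:1000) {
    us <- lapply(blocks, function(b) {
      u <- rnorm(nrow(b)); u / sqrt(sum(u^2))
    })
    h <- rnorm(n); h <- h - mean(h); h <- h / sqrt(sum(h^2 / n))
    best_random <- max(best_random, objective(us, h))
  }
  expect_gte(fit$objective[1], best_random)
})

test_that("MCIA axes are W-orthogonal with non-increasing objectives and
           additive pseudo-eigenvalues", {
  blocks <- small_feature_blocks(n = 12, dims = c(15, 12, 9), seed = 6)
  fit <- mcia_fit(blocks, n_axes = 4)
  H <- fit$synthetic_axes
  G <- t(H) %*% diag(fit$weights) %*% H
  expect_lt(max(abs(G - diag(fit$n_axes))), 1e-8)
  expect_true(all(diff(fit$objective) <= 1e-10))
  expect_equal(colSums(fit$pseudo_eigenvalues), fit$objective,
               tolerance = 1e-8, ignore_attr = TRUE)
  for (u in fit$loadings)
    expect_equal(unname(sqrt(colSums(u^2))), rep(1, fit$n_axes),
                 tolerance = 1e-8)
  expect_true(all(fit$variance_explained >= 0 &
                    fit$variance_explained <= 1))
})

test_that("identical blocks give coincident scores and equal pseudo-eigenvalues", {
  b <- small_feature_blocks(n = 9, dims = 13)[[1]]
  fit <- mcia_fit(list(x = b, y = b, z = b))
  expect_equal(fit$block_scores$x, fit$block_scores$y)
  expect_equal(fit$block_scores$x, fit$block_scores$z)
  expect_equal(fit$centers, fit$block_scores$x)
  expect_lt(max(abs(sweep(fit$pseudo_eigenvalues, 2,
                          fit$pseudo_eigenvalues[1, ]))), 1e-10)
  expect_equal(summed_center_distances(fit)$distance, rep(0, 9),
               tolerance = 1e-10)
})

test_that("MCIA is invariant to permuting one block's features", {
  blocks <- small_feature_blocks(n = 8, dims = c(10, 10), seed = 17)
  perm <- sample(10)
  b2perm <- feature_matrix(unclass(blocks[[2]])[perm, ],
                           standardized = TRUE)
  attr(b2perm, "standardized") <- TRUE
  f1 <- mcia_fit(list(a = blocks[[1]], b = blocks[[2]]))
  f2 <- mcia_fit(list(a = blocks[[1]], b = b2perm))
  expect_equal(f1$objective, f2$objective, tolerance = 1e-10)
  same <- max(abs(f1$synthetic_axes[, 1] - f2$synthetic_axes[, 1]))
  flip <- max(abs(f1$synthetic_axes[, 1] + f2$synthetic_axes[, 1]))
  expect_lt(min(same, flip), 1e-8)
})

test_that("MCIA with S = 2 matches the top eigenvalue of K and ade4's MCOA
           finds the same dominant axis", {
  blocks <- small_feature_blocks(n = 10, dims = c(12, 9), seed = 3)
  fit <- mcia_fit(blocks, n_axes = 1, block_scaling = "none")
  n <- 10
  K <- (crossprod(unclass(blocks[[1]])) + crossprod(unclass(blocks[[2]]))) / n
  expect_equal(fit$objective[1], eigen(K, symmetric = TRUE)$values[1],
               tolerance = 1e-10)

  skip_if_not_installed("ade4")
  # structured blocks so the leading axis is well-separated
  set.seed(10)
  lat <- rnorm(10)
  mk <- function(d) standardize_features(feature_matrix(
    outer(rnorm(d), lat) + 0.3 * matrix(rnorm(d * 10), d, 10)))
  sb <- list(a = mk(12), b = mk(8))
  mine <- mcia_fit(sb, n_axes = 1)
  duds <- lapply(sb, function(b)
    ade4::dudi.pca(as.data.frame(t(unclass(b))), center = FALSE,
                   scale = FALSE, scannf = FALSE, nf = 2))
  mc <- ade4::mcoa(ade4::ktab.list.dudi(duds), scannf = FALSE, nf = 2)
  expect_gt(abs(cor(mine$synthetic_axes[, 1], mc$SynVar[, 1])), 0.99)
})

test_that("single block is rejected with a pointer to PCA", {
  b <- small_feature_blocks(n = 8, dims = 10)[[1]]
  expect_error(mcia_fit(list(b)), "pca_embed")
  expect_error(mcia_fit(list(a = feature_matrix(matrix(1:12, 3)),
                             b = b)), "standardized")
})

test_that("summed center distances are non-negative and rotation-invariant", {
  blocks <- small_feature_blocks(n = 11, dims = c(13, 10, 8), seed = 23)
  fit <- mcia_fit(blocks)
  d0 <- summed_center_distances(fit)
  expect_true(all(d0$distance >= 0))
  # toy arithmetic: center (0,0), scores (3,4) and (0,0) -> 5
  toy <- fit
  toy$centers <- matrix(0, 1, 2, dimnames = list("i1", c("axis1", "axis2")))
  toy$block_scores <- list(a = matrix(c(3, 4), 1), b = matrix(0, 1, 2))
  toy$ids <- "i1"
  expect_equal(summed_center_distances(toy)$distance, 5)
  # jointly rotating all axes leaves the distances unchanged
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- fit
  rot$centers <- fit$centers %*% R
  rot$block_scores <- lapply(fit$block_scores, function(m) m %*% R)
  expect_equal(summed_center_distances(rot)$distance, d0$distance,
               tolerance = 1e-10)
})

test_that("PCA embedding matches the Gram-matrix eigendecomposition", {
  b <- small_feature_blocks(n = 9, dims = 14, seed = 41)[[1]]
  emb <- pca_embed(b, n_axes = 2)
  A <- t(unclass(b)); A <- sweep(A, 2, colMeans(A))
  ev <- eigen(tcrossprod(A), symmetric = TRUE)
  sc <- ev$vectors[, 1:2] %*% diag(sqrt(ev$values[1:2]))
  for (ax in 1:2) {
    got <- cbind(emb$dim1, emb$dim2)[, ax]
    expect_lt(min(max(abs(got - sc[, ax])), max(abs(got + sc[, ax]))), 1e-8)
  }
  ve <- attr(emb, "variance_explained")
  expect_true(all(diff(ve) <= 1e-12))
  expect_lte(sum(ve), 1 + 1e-9)

  # duplicated individual -> identical score rows
  Xd <- unclass(b); Xd <- cbind(Xd, Xd[, 1])
  colnames(Xd) <- c(sprintf("i%02d", seq_len(ncol(b))), "dup")
  embd <- pca_embed(standardize_features(feature_matrix(Xd)))
  expect_equal(unname(c(embd$dim1[10], embd$dim2[10])),
               unname(c(embd$dim1[1], embd$dim2[1])), tolerance = 1e-8)
  expect_error(pca_embed(feature_matrix(matrix(rnorm(4), 2))), "at least 3")
})

test_that("t-SNE is deterministic, improves on early exaggeration, and
           separates well-separated clusters", {
  set.seed(33)
  lab <- rep(c(0, 10), each = 20)
  X <- rbind(outer(rep(1, 8), lab) + matrix(rnorm(8 * 40, sd = 0.3), 8))
  fm <- standardize_features(feature_matrix(X))
  e1 <- tsne_embed(fm, seed = 7, iters = 600)
  e2 <- tsne_embed(fm, seed = 7, iters = 600)
  expect_equal(e1$dim1, e2$dim1)
  expect_equal(e1$dim2, e2$dim2)

  costs <- attr(e1, "itercosts")
  expect_lte(costs[length(costs)], costs[ceiling(250 / 50)] + 1e-9)

  # the two clusters are linearly separable in the embedding
  cl <- lab == 10
  fit <- suppressWarnings(
    stats::glm(cl ~ e1$dim1 + e1$dim2, family = stats::binomial))
  expect_true(all((stats::fitted(fit) > 0.5) == cl))

  expect_error(tsne_embed(fm, perplexity = 30), "infeasible")
})
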