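#' Inertia of a weighted point cloud
#'
#' Total weighted variability `sum_i w_i ||x_i||^2_Q = trace(X'QXW)` of the
#' column cloud of a mean-centered feature matrix. With uniform weights
#' `w_i = 1/n`, identity metric and standardized rows this equals the number
#' of features (a sum of unit variances).
#'
#' @param x feature matrix, features x individuals, rows mean-centered.
#' @param w sample weights (default uniform `1/n`).
#' @param Q optional feature-space metric (`d x d`, symmetric positive
#'   definite); identity if `NULL`.
#' @return scalar inertia.
#' @export
inertia <- function(x, w = NULL, Q = NULL) {
  x <- unclass(as.matrix(x))
  n <- ncol(x)
  if (is.null(w)) w <- rep(1 / n, n)
  if (length(w) != n) stop("length(w) must equal ncol(x)")
  if (is.null(Q)) {
    sum(w * colSums(x^2))
  } else {
    if (!all(dim(Q) == nrow(x))) stop("Q must be d x d")
    sum(w * colSums(x * (Q %*% x)))
  }
}

#' Co-inertia of two matched point clouds
#'
#' Geometric correlation `trace(XQX'WYRY'W)` between two mean-centered
#' feature matrices over the same individuals: the sum of squared
#' W-covariances between all feature pairs. Symmetric in its arguments and
#' non-negative; 0 when the two clouds are W-orthogonal.
#'
#' @param x,y feature matrices (features x individuals) over the same n
#'   individuals.
#' @param w sample weights (default `1/n`).
#' @param Q,R optional feature-space metrics for `x` and `y`.
#' @return scalar co-inertia.
#' @export
coinertia <- function(x, y, w = NULL, Q = NULL, R = NULL) {
  x <- unclass(as.matrix(x)); y <- unclass(as.matrix(y))
  n <- ncol(x)
  if (ncol(y) != n) stop("x and y must have the same number of individuals")
  if (is.null(w)) w <- rep(1 / n, n)
  cx <- if (is.null(Q)) crossprod(x) else t(x) %*% Q %*% x
  cy <- if (is.null(R)) crossprod(y) else t(y) %*% R %*% y
  cxw <- cx * rep(w, each = n)  # C_X %*% diag(w)
  cyw <- cy * rep(w, each = n)
  sum(cxw * t(cyw))
}

#' Multiple co-inertia analysis
#'
#' Projects S standardized feature blocks over the same individuals into one
#' shared low-dimensional space. Axis by axis, MCIA finds block loadings
#' `u_s` (unit norm) and a synthetic axis `h` (unit W-norm) maximizing the
#' sum over blocks of squared covariances `Cov^2(X_s' u_s, h)`. The optimum
#' is the top eigenpair of `K = sum_s W^{1/2} X_s' X_s W^{1/2}`; subsequent
#' axes are obtained after projecting each block onto the W-orthocomplement
#' of `h`, so the synthetic axes are mutually W-orthogonal and the per-axis
#' objectives are the decreasing eigenvalues of K.
#'
#' Block sample scores and the per-individual synthetic centers (the
#' W-weighted mean of the block scores) are rescaled to unit W-variance per
#' axis for plotting; each block's covariance contribution per axis is kept
#' in `pseudo_eigenvalues`.
#'
#' @param blocks named list of standardized `feature_matrix` objects (same
#'   individuals, same column order).
#' @param n_axes number of axes (default 2).
#' @param block_scaling `"unit_inertia"` divides each standardized block by
#'   the square root of its total inertia so feature count does not dictate
#'   block influence; `"none"` leaves blocks as supplied.
#' @return an object of class `mcia`.
#' @export
mcia_fit <- function(blocks, n_axes = 2,
                     block_scaling = c("unit_inertia", "none")) {
  block_scaling <- match.arg(block_scaling)
  S <- length(blocks)
  if (S < 2)
    stop("MCIA needs at least 2 blocks; use pca_embed() for a single block")
  if (is.null(names(blocks)))
    names(blocks) <- sprintf("block%d", seq_len(S))
  std <- vapply(blocks, function(b) isTRUE(attr(b, "standardized")),
                logical(1))
  if (!all(std))
    stop("all blocks must be standardized (see standardize_features())")
  ns <- vapply(blocks, ncol, integer(1))
  if (length(unique(ns)) != 1L) stop("blocks differ in individual count")
  n <- ns[[1]]
  ids <- colnames(blocks[[1]]) %||% sprintf("ind%03d", seq_len(n))
  for (b in blocks)
    if (!is.null(colnames(b)) && !identical(colnames(b), colnames(blocks[[1]])))
      stop("blocks must share the same individuals in the same order")
  w <- rep(1 / n, n)
  Xs <- lapply(blocks, function(b) {
    m <- unclass(as.matrix(b))
    if (block_scaling == "unit_inertia") m / sqrt(inertia(m, w)) else m
  })
  build_K <- function(mats) {
    K <- matrix(0, n, n)
    for (m in mats) K <- K + crossprod(m)
    # W^{1/2} (.) W^{1/2} with uniform weights is a global 1/n factor
    K / n
  }
  total_inertia <- sum(diag(build_K(Xs)))
  h_axes <- matrix(0, n, 0)
  scores <- lapply(Xs, function(m) matrix(0, n, 0))
  loadings <- lapply(Xs, function(m) matrix(0, nrow(m), 0))
  pseudo <- matrix(0, S, 0, dimnames = list(names(blocks), NULL))
  objective <- numeric(0)
  k <- 0
  first_lambda <- NA_real_
  while (k < n_axes) {
    K <- build_K(Xs)
    eig <- eigen(K, symmetric = TRUE)
    lambda <- eig$values[1]
    if (is.na(first_lambda)) first_lambda <- lambda
    if (lambda < 1e-10 * first_lambda) {
      warning(sprintf("rank deficiency: only %d axes available", k))
      break
    }
    v <- eig$vectors[, 1]
    h <- v * sqrt(n)              # W^{-1/2} v, so h' W h = 1
    cs <- lapply(Xs, function(m) as.vector(m %*% (w * h))) # X_s W h
    cov_s <- vapply(cs, function(ci) sqrt(sum(ci^2)), numeric(1))
    us <- mapply(function(ci, cv) if (cv > 0) ci / cv else ci,
                 cs, cov_s, SIMPLIFY = FALSE)
    # deterministic sign: the largest-magnitude loading is positive
    allu <- unlist(us)
    if (allu[which.max(abs(allu))] < 0) {
      h <- -h
      us <- lapply(us, function(u) -u)
      cs <- lapply(cs, function(ci) -ci)
    }
    k <- k + 1
    h_axes <- cbind(h_axes, h)
    objective <- c(objective, lambda)
    pseudo <- cbind(pseudo, cov_s^2)
    for (s in seq_len(S)) {
      scores[[s]] <- cbind(scores[[s]], as.vector(t(Xs[[s]]) %*% us[[s]]))
      loadings[[s]] <- cbind(loadings[[s]], us[[s]])
      Xs[[s]] <- Xs[[s]] - cs[[s]] %*% t(h)   # project out h under W
    }
  }
  axis_names <- sprintf("axis%d", seq_len(k))
  colnames(h_axes) <- axis_names
  colnames(pseudo) <- axis_names
  unit_wvar <- function(m) {
    sdw <- sqrt(colSums(m^2 * w))
    sdw[sdw == 0] <- 1
    sweep(m, 2, sdw, "/")
  }
  scores_std <- lapply(scores, function(m) {
    m <- unit_wvar(m)
    dimnames(m) <- list(ids, axis_names)
    m
  })
  centers_raw <- Reduce(`+`, scores_std) / S
  centers <- unit_wvar(centers_raw)
  dimnames(centers) <- list(ids, axis_names)
  loadings <- lapply(seq_len(S), function(s) {
    m <- loadings[[s]]
    dimnames(m) <- list(rownames(blocks[[s]]), axis_names)
    m
  })
  names(loadings) <- names(blocks)
  structure(list(block_scores = scores_std,
                 block_scores_raw = lapply(scores, function(m) {
                   dimnames(m) <- list(ids, axis_names); m
                 }),
                 synthetic_axes = h_axes,
                 centers = centers,
                 loadings = loadings,
                 pseudo_eigenvalues = pseudo,
                 objective = objective,
                 variance_explained = objective / total_inertia,
                 total_inertia = total_inertia,
                 weights = w, ids = ids,
                 block_scaling = block_scaling,
                 n_axes = k),
            class = "mcia")
}

#' @export
print.mcia <- function(x, ...) {
  cat(sprintf("<mcia> %d blocks (%s), %d individuals, %d axes\n",
              length(x$block_scores),
              paste(names(x$block_scores), collapse = ", "),
              length(x$ids), x$n_axes))
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = ", "),
      "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy MCIA block scores
#'
#' @param x an `mcia` fit.
#' @param ... unused.
#' @return tibble with columns `individual`, `organ`, one column per axis,
#'   plus the synthetic center rows tagged `organ = ".center"`.
#' @export
tidy.mcia <- function(x, ...) {
  rows <- purrr::imap(x$block_scores, function(m, org) {
    tibble::as_tibble(m) |>
      dplyr::mutate(individual = x$ids, organ = org, .before = 1)
  })
  ctr <- tibble::as_tibble(x$centers) |>
    dplyr::mutate(individual = x$ids, organ = ".center", .before = 1)
  dplyr::bind_rows(c(rows, list(ctr)))
}

#' @export
glance.mcia <- function(x, ...) {
  tibble::tibble(
    n_individuals = length(x$ids),
    n_blocks = length(x$block_scores),
    n_axes = x$n_axes,
    objective_axis1 = x$objective[1],
    var_explained_axis1 = x$variance_explained[1],
    var_explained_axis2 = if (x$n_axes >= 2) x$variance_explained[2] else NA_real_)
}

#' Summed distances of block scores to the synthetic center
#'
#' For every individual, the sum over organs of the Euclidean distance (on
#' the first two axes) between that organ's sample score and the
#' individual's common center point. Short distances mean the organs of that
#' individual agree on its location.
#'
#' @param fit an `mcia` fit with at least 2 axes.
#' @return tibble with columns `individual`, `distance`.
#' @export
summed_center_distances <- function(fit) {
  stopifnot(inherits(fit, "mcia"))
  if (fit$n_axes < 2) stop("fit must have at least 2 axes")
  d <- Reduce(`+`, lapply(fit$block_scores, function(m) {
    sqrt(rowSums((m[, 1:2, drop = FALSE] -
                    fit$centers[, 1:2, drop = FALSE])^2))
  }))
  tibble::tibble(individual = fit$ids, distance = unname(d))
}

embedding_2d <- function(coords, method, organ = NULL, ids = NULL,
                         variance_explained = NULL, ...) {
  out <- tibble::tibble(individual = ids %||% sprintf("ind%03d", seq_len(nrow(coords))),
                        dim1 = coords[, 1], dim2 = coords[, 2])
  attr(out, "method") <- method
  attr(out, "organ") <- organ
  attr(out, "variance_explained") <- variance_explained
  extras <- list(...)
  for (nm in names(extras)) attr(out, nm) <- extras[[nm]]
  class(out) <- c("embedding_2d", class(out))
  out
}

#' PCA embedding of one feature matrix
#'
#' Principal component scores of the individuals (column cloud) of a
#' standardized feature matrix. The axis sign is fixed by making the
#' largest-magnitude loading positive, so plots are reproducible.
#'
#' @param x a standardized `feature_matrix` with at least 3 individuals.
#' @param n_axes number of components (default 2).
#' @return a tibble of class `embedding_2d` with columns `individual`,
#'   `dim1`, `dim2` and attributes `method = "pca"`, `variance_explained`.
#' @export
pca_embed <- function(x, n_axes = 2) {
  n <- ncol(x)
  if (n < 3) stop("PCA embedding needs at least 3 individuals")
  a <- t(unclass(as.matrix(x)))
  pc <- stats::prcomp(a, center = TRUE, scale. = FALSE)
  k <- min(n_axes, ncol(pc$x))
  sc <- pc$x[, seq_len(k), drop = FALSE]
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  for (ax in seq_len(k)) {
    if (rot[which.max(abs(rot[, ax])), ax] < 0) {
      rot[, ax] <- -rot[, ax]
      sc[, ax] <- -sc[, ax]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  embedding_2d(sc, method = "pca", organ = attr(x, "organ"),
               ids = colnames(x), variance_explained = ve[seq_len(k)],
               loadings = rot)
}

#' t-SNE embedding of one feature matrix
#'
#' Exact (non-approximated) t-SNE of the individuals: symmetrized
#' conditional affinities at the given perplexity, Student-t low-dimensional
#' kernel, gradient descent with early exaggeration. Deterministic for a
#' fixed seed.
#'
#' @param x a standardized `feature_matrix`.
#' @param perplexity neighbourhood size; default `min(30, floor((n-1)/3))`,
#'   the feasibility bound.
#' @param seed RNG seed for the random initial layout.
#' @param iters gradient-descent iterations (default 1000; early
#'   exaggeration factor 12 for the first 250).
#' @return a tibble of class `embedding_2d`, attribute `itercosts` holding
#'   the KL divergence trace (every 50 iterations).
#' @export
tsne_embed <- function(x, perplexity = NULL, seed = 0, iters = 1000) {
  n <- ncol(x)
  max_perp <- floor((n - 1) / 3)
  if (is.null(perplexity)) perplexity <- min(30, max_perp)
  if (perplexity > max_perp || perplexity < 1)
    stop(sprintf("perplexity %s infeasible for n = %d; maximum is %d",
                 format(perplexity), n, max_perp))
  a <- t(unclass(as.matrix(x)))
  fit <- with_seed(seed,
    Rtsne::Rtsne(a, dims = 2, perplexity = perplexity, theta = 0,
                 max_iter = iters, exaggeration_factor = 12,
                 stop_lying_iter = 250, pca = FALSE, normalize = FALSE,
                 check_duplicates = FALSE, num_threads = 1))
  embedding_2d(fit$Y, method = "tsne", organ = attr(x, "organ"),
               ids = colnames(x), itercosts = fit$itercosts,
               perplexity = perplexity)
}
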