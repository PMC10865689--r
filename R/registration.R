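#' Select the template mesh of an organ set
#'
#' The registration template is the mesh whose enclosed volume (divergence
#' theorem) is closest to the median volume of the set; ties go to the lowest
#' index.
#'
#' @param meshes list of `surface_mesh`.
#' @return integer index into `meshes`.
#' @export
select_template <- function(meshes) {
  if (length(meshes) == 0L) stop("empty mesh list")
  vols <- vapply(meshes, mesh_volume, numeric(1))
  d <- abs(vols - stats::median(vols))
  # ties (to relative rounding) go to the lowest index
  which(d <= min(d) + 1e-9 * max(vols))[1]
}

#' Pairwise Euclidean cost matrix between two point sets
#'
#' @param a,b numeric matrices with matching column count; rows are points.
#' @return `nrow(a) x nrow(b)` matrix of distances.
#' @export
cost_matrix <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

normalize_points <- function(x) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  s <- sqrt(mean(rowSums(xc^2)))
  if (s == 0) s <- 1
  list(x = xc / s, mu = mu, s = s)
}

cpd_probabilities <- function(TX, X, sigma2, w = 0) {
  # TX: moved source (M x D), X: target (N x D)
  D <- ncol(X); M <- nrow(TX); N <- nrow(X)
  d2 <- outer(rowSums(TX^2), rowSums(X^2), "+") - 2 * tcrossprod(TX, X)
  num <- exp(-pmax(d2, 0) / (2 * sigma2))
  c0 <- if (w > 0) (w / (1 - w)) * (2 * pi * sigma2)^(D / 2) * M / N else 0
  den <- colSums(num) + c0 + .Machine$double.xmin
  P <- sweep(num, 2, den, "/")
  nll <- -sum(log(den / M)) + N * D / 2 * log(2 * pi * sigma2)
  list(P = P, nll = nll)
}

#' Affine coherent point drift
#'
#' EM registration of a source point set onto a target, modelling the moved
#' source points as centroids of an isotropic Gaussian mixture. Point sets
#' are internally centred and scaled to unit RMS radius; the returned affine
#' map `x -> B x + t` acts on the original coordinates. Initialization is the
#' identity, so the algorithm is deterministic.
#'
#' @param source,target numeric point matrices (`M x 3` / `N x 3`, or any
#'   common dimension).
#' @param max_iters maximum EM iterations.
#' @param tol stop when the relative change of the negative log-likelihood
#'   falls below this.
#' @param outlier_weight mixture weight of the uniform outlier component
#'   (0 for clean data).
#' @return list with `B`, `t`, `moved` (transformed source), `sigma2`,
#'   `objective` (per-iteration negative log-likelihood) and `converged`.
#' @export
cpd_affine <- function(source, target, max_iters = 100, tol = 1e-5,
                       outlier_weight = 0) {
  Yn <- normalize_points(as.matrix(source))
  Xn <- normalize_points(as.matrix(target))
  Y <- Yn$x; X <- Xn$x
  D <- ncol(X); M <- nrow(Y); N <- nrow(X)
  if (qr(Y)$rank < D || qr(X)$rank < D)
    warning("degenerate (rank-deficient) point set")
  B <- diag(D); tt <- rep(0, D)
  sigma2 <- sum(outer(rowSums(Y^2), rowSums(X^2), "+") -
                  2 * tcrossprod(Y, X)) / (D * M * N)
  obj <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iters)) {
    TY <- sweep(Y %*% t(B), 2, tt, "+")
    e <- cpd_probabilities(TY, X, sigma2, outlier_weight)
    P <- e$P
    obj <- c(obj, e$nll)
    Np <- sum(P)
    P1 <- rowSums(P)   # M
    Pt1 <- colSums(P)  # N
    mu_x <- as.vector(t(X) %*% Pt1) / Np
    mu_y <- as.vector(t(Y) %*% P1) / Np
    Xh <- sweep(X, 2, mu_x)
    Yh <- sweep(Y, 2, mu_y)
    A1 <- t(Xh) %*% t(P) %*% Yh
    A2 <- t(Yh) %*% (Yh * P1)
    B <- A1 %*% solve(A2)
    tt <- mu_x - as.vector(B %*% mu_y)
    sigma2_new <- (sum(Pt1 * rowSums(Xh^2)) - sum(diag(A1 %*% t(B)))) /
      (Np * D)
    sigma2 <- max(sigma2_new, 1e-10)
    if (it > 1 &&
        abs(obj[it - 1] - obj[it]) < tol * (abs(obj[it - 1]) + 1)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("cpd_affine: no convergence within max_iters")
  # compose back to original coordinates
  B_orig <- (Xn$s / Yn$s) * B
  t_orig <- Xn$s * tt + Xn$mu - as.vector(B_orig %*% Yn$mu)
  moved <- sweep(as.matrix(source) %*% t(B_orig), 2, t_orig, "+")
  list(B = B_orig, t = t_orig, moved = moved, sigma2 = sigma2,
       objective = obj, converged = converged)
}

#' Non-rigid coherent point drift
#'
#' Second registration step after [cpd_affine()]: the displacement field is a
#' Gaussian-kernel expansion over the source points (kernel width `beta`),
#' penalized by `lambda` (motion-coherence regularization). Larger `lambda`
#' yields smoother, smaller displacements. Deterministic (identity
#' initialization).
#'
#' @inheritParams cpd_affine
#' @param beta Gaussian kernel width, in units of the normalized (unit RMS
#'   radius) coordinates.
#' @param lambda regularization weight of the displacement field.
#' @return list with `moved`, `sigma2`, `objective`, `converged`.
#' @export
cpd_nonrigid <- function(source, target, beta = 2, lambda = 2,
                         max_iters = 100, tol = 1e-5, outlier_weight = 0) {
  Yn <- normalize_points(as.matrix(source))
  Xn <- normalize_points(as.matrix(target))
  Y <- Yn$x; X <- Xn$x
  D <- ncol(X); M <- nrow(Y); N <- nrow(X)
  d2 <- outer(rowSums(Y^2), rowSums(Y^2), "+") - 2 * tcrossprod(Y)
  G <- exp(-pmax(d2, 0) / (2 * beta^2))
  W <- matrix(0, M, D)
  sigma2 <- sum(outer(rowSums(Y^2), rowSums(X^2), "+") -
                  2 * tcrossprod(Y, X)) / (D * M * N)
  obj <- numeric(0)
  converged <- FALSE
  TY <- Y
  for (it in seq_len(max_iters)) {
    e <- cpd_probabilities(TY, X, sigma2, outlier_weight)
    P <- e$P
    obj <- c(obj, e$nll)
    P1 <- rowSums(P)
    Pt1 <- colSums(P)
    Np <- sum(P1)
    A <- G * P1 + diag(lambda * sigma2, M)
    rhs <- P %*% X - Y * P1
    W <- solve(A, rhs)
    TY <- Y + G %*% W
    sigma2_new <- (sum(Pt1 * rowSums(X^2)) - 2 * sum((P %*% X) * TY) +
                     sum(P1 * rowSums(TY^2))) / (Np * D)
    sigma2 <- max(sigma2_new, 1e-10)
    if (it > 1 &&
        abs(obj[it - 1] - obj[it]) < tol * (abs(obj[it - 1]) + 1)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) warning("cpd_nonrigid: no convergence within max_iters")
  moved <- sweep(TY * Xn$s, 2, Xn$mu, "+")
  list(moved = moved, sigma2 = sigma2, objective = obj,
       converged = converged, displacement = (TY - Y) * Xn$s)
}

#' Optimal vertex correspondence by the Hungarian algorithm
#'
#' Solves the square linear assignment problem whose cost is the Euclidean
#' distance between vertex i of `a` and vertex j of `b`, returning the
#' bijection minimizing the summed cost (exact optimum, not greedy).
#'
#' @param a,b point matrices with equal row counts.
#' @return integer vector `m` with `m[i]` the index in `b` assigned to row
#'   `i` of `a`; attribute `total_cost` carries the minimized sum.
#' @export
hungarian_correspondence <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b))
    stop("point counts differ (", nrow(a), " vs ", nrow(b),
         "); re-decimate both meshes to the same vertex count")
  cm <- cost_matrix(a, b)
  sol <- clue::solve_LSAP(cm)
  m <- as.integer(sol)
  attr(m, "total_cost") <- sum(cm[cbind(seq_len(nrow(cm)), m)])
  m
}

#' Register an organ set to a common template
#'
#' Runs the full per-organ registration: template selection (median volume),
#' two-step coherent point drift (affine, then non-rigid) of every other mesh
#' onto the template, and Hungarian vertex correspondence between the moved
#' vertices and the template vertices. Output meshes all carry the template's
#' vertex ordering, so vertex k is comparable across individuals.
#'
#' @param meshes named list of `surface_mesh`, all with the same vertex
#'   count (decimate first; see [decimate_smooth_center()]).
#' @param template_index optional template override; default
#'   [select_template()].
#' @param beta,lambda non-rigid CPD parameters.
#' @param max_iters,tol CPD stopping parameters.
#' @return a `registered_organ_set`: list with `template_index`, `meshes`
#'   (registered, template vertex ordering) and `transform_log` (tibble).
#' @export
register_organ_set <- function(meshes, template_index = NULL,
                               beta = 2, lambda = 2,
                               max_iters = 100, tol = 1e-5) {
  stopifnot(length(meshes) >= 1)
  if (is.null(names(meshes)))
    names(meshes) <- sprintf("mesh%03d", seq_along(meshes))
  meshes <- lapply(meshes, center_mesh)
  counts <- vapply(meshes, n_vertices, integer(1))
  if (length(unique(counts)) != 1L)
    stop("vertex counts differ; re-decimate all meshes to one count")
  if (is.null(template_index)) template_index <- select_template(meshes)
  tmpl <- meshes[[template_index]]
  out <- vector("list", length(meshes))
  log_rows <- vector("list", length(meshes))
  for (i in seq_along(meshes)) {
    id <- names(meshes)[i]
    if (i == template_index) {
      out[[i]] <- tmpl
      log_rows[[i]] <- tibble::tibble(
        id = id, is_template = TRUE, affine_scale = 1,
        nonrigid_residual = 0, affine_converged = TRUE,
        nonrigid_converged = TRUE)
      next
    }
    src <- meshes[[i]]
    aff <- cpd_affine(src$vertices, tmpl$vertices,
                      max_iters = max_iters, tol = tol)
    nr <- cpd_nonrigid(aff$moved, tmpl$vertices, beta = beta,
                       lambda = lambda, max_iters = max_iters, tol = tol)
    corr <- hungarian_correspondence(nr$moved, tmpl$vertices)
    inv <- integer(length(corr))
    inv[corr] <- seq_along(corr)
    reg <- surface_mesh(nr$moved[inv, , drop = FALSE],
                        matrix(corr[src$faces], ncol = 3))
    out[[i]] <- reg
    log_rows[[i]] <- tibble::tibble(
      id = id, is_template = FALSE,
      affine_scale = det(aff$B)^(1 / 3),
      nonrigid_residual = mean(sqrt(rowSums(nr$displacement^2))),
      affine_converged = aff$converged,
      nonrigid_converged = nr$converged)
  }
  names(out) <- names(meshes)
  structure(list(template_index = template_index, meshes = out,
                 transform_log = dplyr::bind_rows(log_rows)),
            class = "registered_organ_set")
}

#' @export
print.registered_organ_set <- function(x, ...) {
  cat(sprintf("<registered_organ_set> %d meshes, template #%d (%s), %d vertices each\n",
              length(x$meshes), x$template_index,
              names(x$meshes)[x$template_index],
              n_vertices(x$meshes[[1]])))
  invisible(x)
}
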