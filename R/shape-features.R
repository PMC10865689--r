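#' Pointwise mean curvature of a triangle mesh
#'
#' Discrete mean curvature from the cotangent-Laplacian mean-curvature
#' normal: `H = ||L v|| / 2` with barycentric vertex areas, signed by
#' agreement with the inward vertex normal so that convex surface regions are
#' positive (a sphere of radius r has `H = 1/r` everywhere).
#'
#' @param mesh a watertight `surface_mesh` with consistent winding.
#' @return numeric vector of per-vertex mean curvature (1/mm).
#' @export
mean_curvature <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  V <- nrow(v)
  areas <- triangle_areas(mesh)
  degen <- areas < 1e-12 * max(areas, 1e-300)
  if (any(degen))
    warning(sum(degen), " degenerate triangle(s); affected vertices get ",
            "neighbourhood-average curvature")
  lap <- matrix(0, V, 3)
  wsum <- numeric(V)
  varea <- numeric(V)
  for (corner in 1:3) {
    i <- f[, corner]
    j <- f[, corner %% 3 + 1]
    k <- f[, (corner + 1) %% 3 + 1]
    # cot of the angle at i, weighting edge (j, k)
    e1 <- v[j, , drop = FALSE] - v[i, , drop = FALSE]
    e2 <- v[k, , drop = FALSE] - v[i, , drop = FALSE]
    num <- rowSums(e1 * e2)
    cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    den <- sqrt(rowSums(cr^2))
    cot <- ifelse(degen | den < 1e-300, 0, num / den)
    # contributions: L_j += cot * (v_k - v_j); L_k += cot * (v_j - v_k)
    for (d in 1:3) {
      lap[, d] <- lap[, d] +
        tapply_add(cot * (v[k, d] - v[j, d]), j, V) +
        tapply_add(cot * (v[j, d] - v[k, d]), k, V)
    }
    varea <- varea + tapply_add(ifelse(degen, 0, areas) / 3,
                                i, V)
  }
  ok <- varea > 1e-300
  H <- numeric(V)
  lapn <- lap
  lapn[ok, ] <- lap[ok, ] / (2 * varea[ok])
  mag <- sqrt(rowSums(lapn^2)) / 2
  inward <- -vertex_normals(mesh)
  sgn <- sign(rowSums(lapn * inward))
  sgn[sgn == 0] <- 1
  H <- mag * sgn
  if (any(!ok)) {
    # degenerate-area vertices: average over their 1-ring
    e <- unique(mesh_edges(mesh))
    for (bad in which(!ok)) {
      nb <- c(e[e[, 1] == bad, 2], e[e[, 2] == bad, 1])
      nb <- nb[ok[nb]]
      H[bad] <- if (length(nb)) mean(H[nb]) else 0
    }
  }
  H
}

#' Seeded landmark pairs for distance-ratio features
#'
#' Draws `n_pairs` distinct unordered vertex-index pairs uniformly without
#' replacement, reproducibly from `seed`. One fixed pair set is drawn per
#' organ family and reused for every individual, so the resulting features
#' are comparable across the cohort.
#'
#' @param n_vertices number of vertices of the (registered) meshes.
#' @param n_pairs number of pairs (default 500).
#' @param seed integer RNG seed.
#' @return tibble with columns `i`, `j` (`i < j`) and attributes `seed`,
#'   `n_vertices`.
#' @export
sample_landmark_pairs <- function(n_vertices, n_pairs = 500, seed = 42) {
  V <- as.integer(n_vertices)
  total <- as.double(V) * (V - 1) / 2
  if (total < n_pairs)
    stop(sprintf("only %.0f distinct pairs exist for V = %d; cannot draw %d",
                 total, V, n_pairs))
  lin <- with_seed(seed, sample.int(total, n_pairs))
  # invert the row-major upper-triangle linear index
  cum <- cumsum((V - 1):1)
  i <- findInterval(lin - 1, c(0, cum), rightmost.closed = FALSE)
  j <- lin - c(0, cum)[i] + i
  out <- tibble::tibble(i = as.integer(i), j = as.integer(j))
  stopifnot(all(out$i < out$j), !anyDuplicated(out))
  attr(out, "seed") <- seed
  attr(out, "n_vertices") <- V
  out
}

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

mesh_graph <- function(mesh) {
  e <- unique(mesh_edges(mesh))
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                       mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_vertices(mesh) - igraph::vcount(g)))
  igraph::E(g)$weight <- w
  g
}

#' Geodesic distance between mesh vertices
#'
#' Shortest-path length on the mesh edge graph with Euclidean edge weights
#' (Dijkstra). This is an upper bound on the exact polyhedral geodesic,
#' slightly overestimating on coarse meshes.
#'
#' @param mesh a connected `surface_mesh`.
#' @param from,to vertex indices (vectors of equal length are paired).
#' @return numeric distances in mm.
#' @export
geodesic_distance <- function(mesh, from, to) {
  stopifnot(length(from) == length(to))
  g <- mesh_graph(mesh)
  src <- sort(unique(from))
  dst <- sort(unique(to))
  dm <- igraph::distances(g, v = src, to = dst, algorithm = "dijkstra")
  d <- dm[cbind(match(from, src), match(to, dst))]
  if (any(!is.finite(d))) stop("vertices are not connected on the mesh")
  unname(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Euclidean-to-geodesic distance ratios at landmark pairs
#'
#' For each landmark pair, the straight-line distance divided by the
#' on-surface (edge-graph) distance. Ratios lie in (0, 1]: 1 along a straight
#' edge chain, smaller on curved or folded surface regions.
#'
#' @param mesh a connected `surface_mesh`.
#' @param pairs landmark pairs from [sample_landmark_pairs()].
#' @return numeric vector, one ratio per pair.
#' @export
euclid_geodesic_ratios <- function(mesh, pairs) {
  if (any(pairs$i == pairs$j)) stop("landmark pairs must have i != j")
  geo <- geodesic_distance(mesh, pairs$i, pairs$j)
  euc <- sqrt(rowSums((mesh$vertices[pairs$i, , drop = FALSE] -
                         mesh$vertices[pairs$j, , drop = FALSE])^2))
  ratio <- euc / geo
  pmin(ratio, 1)
}

#' Surface-area-to-volume ratio
#'
#' @param mesh a watertight `surface_mesh`.
#' @return scalar ratio in 1/mm (3/r for a sphere of radius r).
#' @export
area_volume_ratio <- function(mesh) {
  if (!is_watertight(mesh)) stop("mesh is not watertight")
  mesh_area(mesh) / mesh_volume(mesh)
}

#' Per-organ shape feature matrix
#'
#' Builds the `d x n` feature matrix of one organ over a cohort in vertex
#' correspondence: per-vertex mean curvature (V features), the
#' Euclidean-to-geodesic ratios at the organ's landmark pairs (`n_pairs`
#' features), and the surface-area-to-volume ratio (1 feature), so
#' `d = V + n_pairs + 1` (1501 features at the default 1000 vertices and 500
#' pairs).
#'
#' @param registered a `registered_organ_set`, or a list of `surface_mesh`
#'   already in vertex correspondence.
#' @param pairs landmark pairs from [sample_landmark_pairs()].
#' @param organ organ name stored with the matrix.
#' @return a `feature_matrix`: numeric matrix (features x individuals) with
#'   feature row names, individual column names, and attributes `organ` and
#'   `standardized`.
#' @export
build_feature_matrix <- function(registered, pairs, organ = "organ") {
  meshes <- if (inherits(registered, "registered_organ_set"))
    registered$meshes else registered
  stopifnot(length(meshes) >= 1)
  counts <- vapply(meshes, n_vertices, integer(1))
  if (length(unique(counts)) != 1L)
    stop("meshes are not in correspondence (differing vertex counts)")
  V <- counts[[1]]
  if (max(pairs$j) > V) stop("landmark pairs exceed vertex count")
  ids <- names(meshes) %||% sprintf("ind%03d", seq_along(meshes))
  cols <- lapply(meshes, function(m) {
    c(mean_curvature(m), euclid_geodesic_ratios(m, pairs),
      area_volume_ratio(m))
  })
  X <- do.call(cbind, cols)
  rownames(X) <- c(sprintf("curv_%04d", seq_len(V)),
                   sprintf("ratio_%04d", seq_len(nrow(pairs))),
                   "area_vol")
  colnames(X) <- ids
  feature_matrix(X, organ = organ, standardized = FALSE)
}

#' Feature matrix container
#'
#' @param x numeric matrix, features in rows, individuals in columns.
#' @param organ organ name.
#' @param standardized logical flag.
#' @return a `feature_matrix`.
#' @export
feature_matrix <- function(x, organ = "organ", standardized = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  structure(x, class = c("feature_matrix", "matrix", "array"),
            organ = organ, standardized = standardized)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> organ '%s': %d features x %d individuals%s\n",
              attr(x, "organ"), nrow(x), ncol(x),
              if (isTRUE(attr(x, "standardized"))) ", standardized" else ""))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.feature_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame.matrix(unclass(x)), rownames = "feature")
}

#' Row-standardize a feature matrix
#'
#' Centers every feature (row) and scales it to unit population variance
#' (divisor n, not n - 1, so that the total inertia of the standardized
#' matrix under uniform weights equals the feature count exactly). Rows with
#' zero variance are dropped with a warning. Idempotent.
#'
#' @param x a `feature_matrix` (or plain matrix) with at least 2 columns.
#' @return standardized `feature_matrix`.
#' @export
standardize_features <- function(x) {
  n <- ncol(x)
  if (n < 2) stop("need at least 2 individuals to standardize")
  organ <- attr(x, "organ") %||% "organ"
  m <- unclass(x)
  mu <- rowMeans(m)
  m <- m - mu
  sdp <- sqrt(rowSums(m^2) / n)
  keep <- sdp > 1e-12 * (max(sdp) + 1e-300)
  if (!all(keep))
    warning(sum(!keep), " zero-variance feature(s) dropped")
  m <- m[keep, , drop = FALSE] / sdp[keep]
  feature_matrix(m, organ = organ, standardized = TRUE)
}

#' Write / read a feature matrix as CSV
#'
#' CSV layout: one row per feature, first column `feature` holds the feature
#' name, remaining columns are individuals (header row carries their IDs).
#'
#' @param x a `feature_matrix`.
#' @param path CSV path.
#' @param organ organ name to attach on reading.
#' @return `read_feature_matrix()` returns a `feature_matrix`.
#' @export
write_feature_matrix <- function(x, path) {
  readr::write_csv(as_tibble.feature_matrix(x), path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path, organ = "organ") {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(tb[, -1, drop = FALSE])
  rownames(m) <- tb[[1]]
  feature_matrix(m, organ = organ)
}
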