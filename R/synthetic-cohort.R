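# Smooth radial basis on the unit sphere: degree-2 and degree-3 harmonics
# only. Degree-1 terms are deliberately absent -- to first order they
# translate the shape, and translation is removed by mean-centering and is
# invisible to curvature/ratio/area-volume features.
radial_basis <- function(u) {
  x <- u[, 1]; y <- u[, 2]; z <- u[, 3]
  b <- cbind(x * y, y * z, z * x,
             (x^2 - y^2) / 2, (3 * z^2 - 1) / 2,
             x * y * z,
             z * (5 * z^2 - 3) / 2,
             x * (5 * z^2 - 1) / 2)
  # normalize each basis function to unit maximum magnitude on the sphere so
  # coefficients read as relative radius amplitudes
  sweep(b, 2, apply(abs(b), 2, max), "/")
}

n_radial_basis <- 8L

# deterministic latent-to-coefficient patterns: factor l feeds a fixed
# disjoint group of basis functions
latent_patterns <- function(latent_dim) {
  P <- matrix(0, n_radial_basis, latent_dim)
  groups <- split(seq_len(n_radial_basis),
                  rep(seq_len(latent_dim), length.out = n_radial_basis))
  for (l in seq_len(latent_dim))
    P[groups[[l]], l] <- 1 / sqrt(length(groups[[l]]))
  P
}

#' Specification of a synthetic multi-organ cohort
#'
#' Describes a cohort of individuals, each with one star-shaped closed
#' surface per organ family. Organ shapes share per-individual latent
#' deformation factors (scaled by each organ's loading), so organ shapes are
#' correlated within an individual; independent per-coefficient noise adds
#' organ-specific variation. Planted outliers get all deformation
#' coefficients multiplied by `kappa`, either for a single organ or for
#' every organ of an individual.
#'
#' @param n_individuals cohort size (default 30).
#' @param organs tibble or data frame with columns `name`, `radius_x`,
#'   `radius_y`, `radius_z` (base ellipsoid semi-axes, mm), `loading`
#'   (latent factor scale) and optionally `sigma_d` (coefficient noise sd).
#'   Default: three organ families at liver/kidney/spleen-like scales.
#' @param latent_dim number of shared latent factors per individual
#'   (default 2).
#' @param latent_amplitude relative-radius amplitude of each latent factor
#'   (length `latent_dim`; default `c(0.04, 0.012)`: a dominant first
#'   variation mode, as organ shape-model studies typically report).
#' @param sigma_d default per-coefficient independent noise sd (relative
#'   radius; default 0.004, subordinate to the shared factors).
#' @param outliers tibble with columns `individual` (index), `organ` (organ
#'   name or `"ALL"`), `kappa` (amplitude multiplier).
#' @param n_vertices vertices per mesh (default 1000).
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return a `cohort_spec`.
#' @export
cohort_spec <- function(n_individuals = 30,
                        organs = NULL,
                        latent_dim = 2,
                        latent_amplitude = c(0.04, 0.012),
                        sigma_d = 0.004,
                        outliers = NULL,
                        n_vertices = 1000,
                        seed = 1) {
  if (is.null(organs)) {
    organs <- tibble::tibble(
      name = c("liver", "kidney", "spleen"),
      radius_x = c(80, 35, 45),
      radius_y = c(60, 25, 30),
      radius_z = c(50, 55, 35),
      loading = 1)
  }
  organs <- tibble::as_tibble(organs)
  if (!"sigma_d" %in% names(organs)) organs$sigma_d <- sigma_d
  if (!"loading" %in% names(organs)) organs$loading <- 1
  stopifnot(all(organs$sigma_d >= 0), n_individuals >= 1,
            length(latent_amplitude) == latent_dim,
            all(latent_amplitude >= 0))
  if (is.null(outliers))
    outliers <- tibble::tibble(individual = integer(), organ = character(),
                               kappa = numeric())
  outliers <- tibble::as_tibble(outliers)
  stopifnot(all(outliers$kappa >= 0))
  structure(list(n_individuals = as.integer(n_individuals),
                 organs = organs,
                 latent_dim = as.integer(latent_dim),
                 latent_amplitude = latent_amplitude,
                 outliers = outliers,
                 n_vertices = as.integer(n_vertices),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d individuals x %d organs (%s), %d vertices, %d outlier(s), seed %d\n",
              x$n_individuals, nrow(x$organs),
              paste(x$organs$name, collapse = ", "),
              x$n_vertices, nrow(x$outliers), x$seed))
  invisible(x)
}

# fixed sphere triangulation at the requested vertex budget, shared by every
# mesh of the cohort so vertex correspondence holds by construction
unit_sphere_mesh <- function(n_vertices) {
  counts <- c(12, 42, 162, 642, 2562, 10242)
  level <- which(counts >= n_vertices)[1]
  if (is.na(level)) stop("n_vertices too large")
  base <- icosphere(level - 1)
  if (n_vertices(base) > n_vertices) {
    dec <- .cpp_decimate_quadric(base$vertices, base$faces,
                                 as.integer(n_vertices))
    base <- surface_mesh(dec$vertices, dec$faces)
    # re-project decimated vertices onto the unit sphere
    base$vertices <- base$vertices / sqrt(rowSums(base$vertices^2))
  }
  base
}

#' Generate a synthetic multi-organ cohort
#'
#' Builds, fully deterministically from the spec's seed, one star-shaped
#' triangulated surface per individual and organ:
#' `r(u) = r_ellipsoid(u) * (1 + sum_k a_k B_k(u))` over a fixed sphere
#' triangulation, where the `B_k` are smooth low-order radial basis
#' functions and the coefficients mix shared latent factors (times the organ
#' loading) with independent noise. All meshes of one cohort share the same
#' triangulation, so they are in exact vertex correspondence.
#'
#' @param spec a [cohort_spec()].
#' @return list with `meshes` (list organ -> list of `surface_mesh` named by
#'   individual), `truth` (tibble: individual, latent factor columns,
#'   outlier flags per organ) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  sph <- unit_sphere_mesh(spec$n_vertices)
  u <- sph$vertices
  B <- radial_basis(u)
  P <- latent_patterns(spec$latent_dim)
  n <- spec$n_individuals
  ids <- sprintf("ind%03d", seq_len(n))
  out <- with_seed(spec$seed, {
    Z <- matrix(stats::rnorm(n * spec$latent_dim), n, spec$latent_dim)
    noise <- lapply(seq_len(nrow(spec$organs)), function(s)
      matrix(stats::rnorm(n * n_radial_basis, sd = spec$organs$sigma_d[s]),
             n, n_radial_basis))
    list(Z = Z, noise = noise)
  })
  Z <- out$Z
  kappa_of <- function(i, organ) {
    ot <- spec$outliers
    hit <- ot[ot$individual == i & (ot$organ == organ | ot$organ == "ALL"), ]
    if (nrow(hit)) prod(hit$kappa) else 1
  }
  meshes <- list()
  flags <- matrix(FALSE, n, nrow(spec$organs),
                  dimnames = list(ids, spec$organs$name))
  for (s in seq_len(nrow(spec$organs))) {
    org <- spec$organs[s, ]
    re <- 1 / sqrt(u[, 1]^2 / org$radius_x^2 + u[, 2]^2 / org$radius_y^2 +
                     u[, 3]^2 / org$radius_z^2)
    organ_meshes <- vector("list", n)
    for (i in seq_len(n)) {
      a <- org$loading * as.vector(P %*% (spec$latent_amplitude * Z[i, ])) +
        out$noise[[s]][i, ]
      kap <- kappa_of(i, org$name)
      if (kap != 1) flags[i, s] <- TRUE
      a <- a * kap
      rad <- re * (1 + as.vector(B %*% a))
      if (any(rad <= 0))
        stop("deformation too large: non-positive radius for individual ",
             i, ", organ ", org$name)
      organ_meshes[[i]] <- surface_mesh(rad * u, sph$faces)
    }
    names(organ_meshes) <- ids
    meshes[[org$name]] <- organ_meshes
  }
  truth <- tibble::as_tibble(Z, .name_repair = ~sprintf("latent%d", seq_len(spec$latent_dim)))
  truth <- dplyr::bind_cols(tibble::tibble(individual = ids), truth)
  for (org in spec$organs$name)
    truth[[paste0("outlier_", org)]] <- unname(flags[, org])
  list(meshes = meshes, truth = truth, spec = spec)
}

#' Voxelize meshes into a label volume
#'
#' Rasterizes watertight meshes onto a voxel grid by ray-casting parity
#' along the first axis, writing each organ's code into a shared label
#' image. Organs are laid out side by side along the first axis (synthetic
#' organs are generated about a common centroid, and overlapping codes
#' would clobber each other); relative organ placement carries no signal in
#' this pipeline. Intended to exercise the volume-to-mesh path on synthetic
#' data.
#'
#' @param meshes named list of `surface_mesh` (one per organ).
#' @param codes named integer vector of organ codes (default 1, 2, ...).
#' @param spacing voxel spacing in mm.
#' @param margin empty border in voxels.
#' @return a `label_volume`.
#' @export
voxelize_meshes <- function(meshes, codes = NULL, spacing = c(4, 4, 4),
                            margin = 2) {
  stopifnot(length(meshes) >= 1)
  if (is.null(names(meshes)))
    names(meshes) <- sprintf("organ%d", seq_along(meshes))
  if (is.null(codes))
    codes <- stats::setNames(seq_along(meshes), names(meshes))
  # shift each organ along x so the label regions cannot overlap
  xmax <- -Inf
  meshes <- lapply(meshes, function(m) {
    lo <- min(m$vertices[, 1])
    shift <- if (is.finite(xmax)) (xmax - lo) + 2 * spacing[1] else 0
    m$vertices[, 1] <- m$vertices[, 1] + shift
    xmax <<- max(m$vertices[, 1])
    m
  })
  allv <- do.call(rbind, lapply(meshes, function(m) m$vertices))
  lo <- apply(allv, 2, min) - margin * spacing
  hi <- apply(allv, 2, max) + margin * spacing
  dims <- pmax(ceiling((hi - lo) / spacing) + 1, 2)
  vox <- array(0L, dims)
  xs <- lo[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- lo[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- lo[3] + (seq_len(dims[3]) - 1) * spacing[3]
  for (nm in names(meshes)) {
    m <- meshes[[nm]]
    v1 <- face_corner(m, 1); v2 <- face_corner(m, 2); v3 <- face_corner(m, 3)
    for (jy in seq_along(ys)) for (kz in seq_along(zs)) {
      y0 <- ys[jy]; z0 <- zs[kz]
      # triangles whose (y, z) projection contains the ray
      d1 <- (v2[, 2] - v1[, 2]) * (z0 - v1[, 3]) - (v2[, 3] - v1[, 3]) * (y0 - v1[, 2])
      d2 <- (v3[, 2] - v2[, 2]) * (z0 - v2[, 3]) - (v3[, 3] - v2[, 3]) * (y0 - v2[, 2])
      d3 <- (v1[, 2] - v3[, 2]) * (z0 - v3[, 3]) - (v1[, 3] - v3[, 3]) * (y0 - v3[, 2])
      hit <- which((d1 >= 0 & d2 >= 0 & d3 >= 0) | (d1 <= 0 & d2 <= 0 & d3 <= 0))
      if (!length(hit)) next
      xints <- vapply(hit, function(f) {
        tri <- rbind(v1[f, ], v2[f, ], v3[f, ])
        # barycentric solve in the (y, z) plane
        A <- cbind(tri[2, 2:3] - tri[1, 2:3], tri[3, 2:3] - tri[1, 2:3])
        det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
        if (abs(det) < 1e-14) return(NA_real_)
        rhs <- c(y0 - tri[1, 2], z0 - tri[1, 3])
        b1 <- (rhs[1] * A[2, 2] - A[1, 2] * rhs[2]) / det
        b2 <- (A[1, 1] * rhs[2] - rhs[1] * A[2, 1]) / det
        tri[1, 1] + b1 * (tri[2, 1] - tri[1, 1]) + b2 * (tri[3, 1] - tri[1, 1])
      }, numeric(1))
      xints <- sort(xints[is.finite(xints)])
      if (length(xints) < 2) next
      # parity fill between successive crossing pairs
      for (pair in seq_len(floor(length(xints) / 2))) {
        inside <- xs >= xints[2 * pair - 1] & xs <= xints[2 * pair]
        vox[inside, jy, kz] <- codes[[nm]]
      }
    }
  }
  label_volume(vox, spacing = spacing, organ_codes = codes)
}
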