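test_that("mean curvature matches the analytic sphere value and scaling", {
  s1 <- icosphere(4) # ~2562 vertices
  H1 <- mean_curvature(s1)
  expect_lt(abs(mean(H1) - 1), 0.05)
  expect_true(all(H1 > 0)) # convex surface, positive by convention

  s2 <- icosphere(4, radius = 2)
  expect_lt(abs(mean(mean_curvature(s2)) - 0.5), 0.025)
})

test_that("mean curvature vanishes on the flat interior of a box face", {
  mask <- array(0L, c(26, 26, 5))
  mask[2:25, 2:25, 2:4] <- 1L
  box <- extract_mesh(mask, c(1, 1, 1))
  H <- mean_curvature(box)
  v <- box$vertices
  interior_top <- which(abs(v[, 3] - max(v[, 3])) < 1e-9 &
                          v[, 1] > 8 & v[, 1] < 18 &
                          v[, 2] > 8 & v[, 2] < 18)
  expect_gt(length(interior_top), 10)
  expect_lt(max(abs(H[interior_top])), 1e-6)
})

test_that("landmark pair sampling is seeded, distinct and bounded", {
  p1 <- sample_landmark_pairs(1000, 500, seed = 42)
  p2 <- sample_landmark_pairs(1000, 500, seed = 42)
  expect_identical(p1$i, p2$i)
  expect_identical(p1$j, p2$j)
  expect_equal(nrow(p1), 500L)
  expect_true(all(p1$i < p1$j))
  expect_false(any(duplicated(paste(p1$i, p1$j))))
  expect_true(all(p1$j <= 1000))
  p3 <- sample_landmark_pairs(1000, 500, seed = 43)
  expect_false(identical(p1$i, p3$i) && identical(p1$j, p3$j))
  expect_error(sample_landmark_pairs(3, 4), "cannot draw")
})

test_that("geodesic distances behave like the graph metric", {
  s <- icosphere(4)
  e <- unique(morphomcia:::mesh_edges(s))
  # adjacent vertices: geodesic equals the edge length
  i <- e[1, 1]; j <- e[1, 2]
  expect_equal(geodesic_distance(s, i, j),
               sqrt(sum((s$vertices[i, ] - s$vertices[j, ])^2)),
               tolerance = 1e-12)
  expect_equal(geodesic_distance(s, 5L, 5L), 0)

  # antipodal pair on the unit sphere: graph path overestimates pi slightly
  v1 <- s$vertices[1, ]
  anti <- which.min(rowSums(sweep(s$vertices, 2, -v1)^2))
  g <- geodesic_distance(s, 1L, anti)
  expect_lt(abs(g - pi) / pi, 0.06)
  expect_gte(g, pi) # an upper bound on the true geodesic
})

test_that("Euclid/geodesic ratios live in (0, 1] with the sphere value", {
  s <- icosphere(4)
  pr <- sample_landmark_pairs(n_vertices(s), 400, seed = 11)
  ratios <- euclid_geodesic_ratios(s, pr)
  expect_true(all(ratios > 0 & ratios <= 1))

  v1 <- s$vertices[1, ]
  anti <- which.min(rowSums(sweep(s$vertices, 2, -v1)^2))
  rr <- euclid_geodesic_ratios(s, tibble::tibble(i = 1L, j = anti))
  expect_lt(abs(rr - 2 / pi), 0.05)

  bad <- tibble::tibble(i = 3L, j = 3L)
  expect_error(euclid_geodesic_ratios(s, bad), "i != j")
})

test_that("area/volume ratio matches closed forms and scaling", {
  s <- icosphere(4)
  expect_lt(abs(area_volume_ratio(s) - 3) / 3, 0.02)
  expect_equal(area_volume_ratio(unit_cube_mesh(2)), 3, tolerance = 1e-12)
  s2 <- icosphere(4, radius = 2)
  expect_equal(area_volume_ratio(s2), area_volume_ratio(s) / 2,
               tolerance = 1e-9)
  open_mesh <- surface_mesh(s$vertices, s$faces[-1, ])
  expect_error(area_volume_ratio(open_mesh), "watertight")
})

test_that("feature matrix has d = V + n_pairs + 1 rows and is consistent", {
  sim <- generate_cohort(cohort_spec(n_individuals = 4, seed = 31,
                                     n_vertices = 162))
  meshes <- sim$meshes$spleen
  pr <- sample_landmark_pairs(162, 20, seed = 1)
  X <- build_feature_matrix(meshes, pr, organ = "spleen")
  expect_equal(dim(X), c(162 + 20 + 1, 4))
  expect_equal(rownames(X)[163], "ratio_0001")
  expect_equal(rownames(X)[183], "area_vol")

  # duplicated individual gives identical columns
  dup <- c(meshes, meshes[1])
  names(dup)[5] <- "copy"
  Xd <- build_feature_matrix(dup, pr)
  expect_equal(unname(Xd[, 5]), unname(Xd[, 1]))

  mixed <- c(meshes[1:2], list(other = icosphere(1)))
  expect_error(build_feature_matrix(mixed, pr), "correspondence")
})

test_that("features are invariant to rigid translation of all meshes", {
  sim <- generate_cohort(cohort_spec(n_individuals = 3, seed = 8,
                                     n_vertices = 162))
  meshes <- sim$meshes$kidney
  pr <- sample_landmark_pairs(162, 25, seed = 2)
  X0 <- build_feature_matrix(meshes, pr)
  moved <- lapply(meshes, function(m)
    surface_mesh(sweep(m$vertices, 2, c(12, -5, 30), "+"), m$faces))
  X1 <- build_feature_matrix(moved, pr)
  expect_equal(unclass(X1), unclass(X0), tolerance = 1e-9)
})

test_that("standardization gives exact zero mean, unit population variance", {
  set.seed(2)
  X <- feature_matrix(matrix(rnorm(60, sd = 4, mean = 3), 6, 10))
  Z <- standardize_features(X)
  expect_lt(max(abs(rowMeans(Z))), 1e-10)
  expect_lt(max(abs(rowSums(unclass(Z)^2) / ncol(Z) - 1)), 1e-10)
  expect_true(attr(Z, "standardized"))
  # inertia identity: standardized rows sum to the feature count
  expect_equal(inertia(Z), nrow(Z), tolerance = 1e-8)

  # constant row dropped with warning; idempotence
  Xc <- feature_matrix(rbind(unclass(X), rep(7, 10)))
  expect_warning(Zc <- standardize_features(Xc), "zero-variance")
  expect_equal(nrow(Zc), nrow(X))
  expect_equal(unclass(standardize_features(Z)), unclass(Z),
               tolerance = 1e-12)
  expect_error(standardize_features(feature_matrix(matrix(1, 3, 1))),
               "at least 2")
})

test_that("feature matrices round-trip through CSV", {
  X <- feature_matrix(matrix(rnorm(12), 4, 3,
                             dimnames = list(paste0("f", 1:4),
                                             paste0("ind", 1:3))),
                      organ = "liver")
  tf <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(X, tf)
  back <- read_feature_matrix(tf, organ = "liver")
  expect_equal(unclass(back), unclass(X), tolerance = 1e-12)
})
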