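test_that("template selection picks the volume nearest the median", {
  sph <- function(r) icosphere(1, radius = r)
  vols_to_meshes <- function(radii) lapply(radii, sph)
  # volumes scale as r^3: radii chosen so volumes are 1,2,3,4,100 units
  radii <- c(1, 2, 3, 4, 100)^(1 / 3)
  expect_equal(select_template(vols_to_meshes(radii)), 3L)
  # even count: median 2.5, tie between 2 and 3 -> lowest index
  expect_equal(select_template(vols_to_meshes(c(1, 2, 3, 4)^(1 / 3))), 2L)
  expect_equal(select_template(list(sph(1))), 1L)
  expect_error(select_template(list()), "empty")
})

test_that("affine CPD is exact on identity and recovers a known transform", {
  set.seed(7)
  Y <- matrix(rnorm(900), 300, 3)
  fit0 <- cpd_affine(Y, Y)
  expect_lt(max(abs(fit0$B - diag(3))), 1e-5)
  expect_lt(sqrt(sum(fit0$t^2)), 1e-6 * bbox_diagonal(Y))

  B0 <- matrix(c(1.2, 0.2, 0, -0.1, 0.9, 0.05, 0, 0.1, 1.1), 3, byrow = TRUE)
  t0 <- c(2, -1, 0.5)
  X <- sweep(Y %*% t(B0), 2, t0, "+")
  fit <- cpd_affine(Y, X)
  rmsd <- sqrt(mean(rowSums((fit$moved - X)^2)))
  expect_lt(rmsd, 1e-3 * bbox_diagonal(X))

  # noisy target: stay within twice the noise level
  sigma <- 0.02 * bbox_diagonal(X)
  Xn <- X + matrix(rnorm(length(X), sd = sigma), nrow(X))
  fitn <- cpd_affine(Y, Xn)
  expect_lt(sqrt(mean(rowSums((fitn$moved - X)^2))), 2 * sigma)
})

test_that("affine CPD objective is non-increasing", {
  set.seed(12)
  Y <- matrix(rnorm(300), 100, 3)
  X <- sweep(Y %*% t(diag(3) + 0.1 * matrix(rnorm(9), 3)), 2, c(1, 0, -1), "+")
  fit <- cpd_affine(Y, X)
  expect_true(all(diff(fit$objective) <=
                    1e-6 * (abs(fit$objective[-length(fit$objective)]) + 1)))
})

test_that("non-rigid CPD flattens a smooth bump and respects regularization", {
  sph <- icosphere(3)
  Y <- sph$vertices
  expect_lt(max(sqrt(rowSums((cpd_nonrigid(Y, Y)$moved - Y)^2))),
            1e-6 * bbox_diagonal(Y))

  bump <- exp(-rowSums(sweep(Y, 2, c(0, 0, 1))^2) / 0.3)
  X <- Y * (1 + 0.05 * bump)
  fit <- cpd_nonrigid(Y, X)
  expect_lt(sqrt(mean(rowSums((fit$moved - X)^2))), 0.01 * bbox_diagonal(X))

  # 100x more regularization cannot make the displacement field rougher
  roughness <- function(moved) {
    disp <- moved - Y
    sum(diff(diff(disp[order(Y[, 1]), 1]))^2) +
      sum(diff(diff(disp[order(Y[, 2]), 2]))^2)
  }
  stiff <- cpd_nonrigid(Y, X, lambda = 200)
  expect_lte(roughness(stiff$moved), roughness(fit$moved) + 1e-9)
})

test_that("Hungarian correspondence is optimal", {
  # the 2x2 case, checked against both permutations by hand
  a <- rbind(c(0, 0), c(1, 0))
  b <- rbind(c(0, 1), c(1, 1))
  m <- hungarian_correspondence(a, b)
  expect_equal(as.integer(m), c(1L, 2L))
  expect_equal(attr(m, "total_cost"), 2)

  # identical points: identity, zero cost
  set.seed(4)
  p <- matrix(rnorm(20), 10, 2)
  mid <- hungarian_correspondence(p, p)
  expect_equal(as.integer(mid), 1:10)
  expect_equal(attr(mid, "total_cost"), 0)

  # exhaustive oracle at n = 6 and n = 7
  for (n in c(6, 7)) {
    a <- matrix(rnorm(2 * n), n, 2)
    b <- matrix(rnorm(2 * n), n, 2)
    mm <- hungarian_correspondence(a, b)
    expect_equal(attr(mm, "total_cost"),
                 brute_assignment_cost(cost_matrix(a, b)), tolerance = 1e-12)
    # never worse than identity or random bijections
    cm <- cost_matrix(a, b)
    expect_lte(attr(mm, "total_cost"), sum(diag(cm)))
    for (r in 1:20)
      expect_lte(attr(mm, "total_cost"),
                 sum(cm[cbind(seq_len(n), sample(n))]))
  }
  expect_error(hungarian_correspondence(matrix(0, 3, 2), matrix(0, 4, 2)),
               "re-decimate")
})

test_that("organ-set registration yields corresponded meshes and is
           translation-invariant", {
  sim <- generate_cohort(cohort_spec(n_individuals = 3, seed = 9,
                                     n_vertices = 162))
  meshes <- sim$meshes$kidney
  reg <- register_organ_set(meshes)
  counts <- vapply(reg$meshes, n_vertices, integer(1))
  expect_true(all(counts == counts[[1]]))
  expect_equal(nrow(reg$transform_log), 3L)
  expect_true(all(reg$transform_log$affine_converged))

  # pre-translating one source changes nothing (meshes are centered first)
  shifted <- meshes
  shifted[[1]]$vertices <- sweep(shifted[[1]]$vertices, 2, c(50, -20, 10), "+")
  reg2 <- register_organ_set(shifted)
  expect_equal(reg2$meshes[[1]]$vertices, reg$meshes[[1]]$vertices,
               tolerance = 1e-6)

  uneven <- c(meshes[1:2], list(extra = icosphere(3)))
  expect_error(register_organ_set(uneven), "re-decimate")
})
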