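test_that("slice cleaning fills enclosed holes and removes speckle", {
  # interior hole in a solid block large enough to survive the 5x5 opening
  sl <- matrix(0L, 21, 21)
  sl[5:17, 5:17] <- 1L
  sl[11, 11] <- 0L
  mask <- array(0L, c(21, 21, 3))
  mask[, , 2] <- sl
  out <- clean_mask_slices(mask)
  expect_equal(out[11, 11, 2], 1L)
  expect_equal(sum(out[, , 2]), 13L * 13L)

  # isolated 2x2 island is annihilated by the 5x5 opening
  sl2 <- matrix(0L, 20, 20)
  sl2[3:4, 3:4] <- 1L
  sl2[10:16, 10:16] <- 1L
  mask2 <- array(sl2, c(20, 20, 1))
  out2 <- clean_mask_slices(mask2)
  expect_equal(sum(out2[3:4, 3:4, 1]), 0L)
  expect_gt(sum(out2[10:16, 10:16, 1]), 0L)

  # all-zero slice passes through; non-binary input errors
  zero <- array(0L, c(8, 8, 2))
  expect_equal(clean_mask_slices(zero), zero)
  expect_error(clean_mask_slices(array(2L, c(4, 4, 1))), "binary")
})

test_that("slice cleaning is idempotent", {
  set.seed(21)
  mask <- array(as.integer(runif(16 * 16 * 4) > 0.55), c(16, 16, 4))
  once <- clean_mask_slices(mask)
  expect_identical(clean_mask_slices(once), once)
})

test_that("extract_mesh recovers volume and keeps the largest blob", {
  mask <- array(0L, c(12, 12, 12))
  mask[2:11, 2:11, 2:11] <- 1L
  m <- extract_mesh(mask, c(1, 1, 1))
  expect_true(is_watertight(m))
  expect_equal(euler_characteristic(m), 2)
  expect_lt(abs(mesh_volume(m) - 1000) / 1000, 0.15)

  # two blobs: only the larger is kept
  mask2 <- array(0L, c(24, 10, 10))
  mask2[2:11, 2:9, 2:9] <- 1L       # 10x8x8 = 640 voxels
  mask2[16:17, 4:5, 4:5] <- 1L      # 8 voxels
  m2 <- extract_mesh(mask2, c(1, 1, 1))
  expect_length(mesh_components(m2), 1L)
  expect_true(all(m2$vertices[, 1] < 14))

  # single voxel still gives a small closed mesh
  mask3 <- array(0L, c(3, 3, 3)); mask3[2, 2, 2] <- 1L
  m3 <- extract_mesh(mask3, c(1, 1, 1))
  expect_true(is_watertight(m3))
  expect_gt(mesh_volume(m3), 0)

  expect_error(extract_mesh(array(0L, c(4, 4, 4))), "empty organ mask")
})

test_that("extract_mesh stays watertight and single-component for blobs", {
  set.seed(5)
  for (rep in 1:3) {
    ctr <- c(8, 8, 8); radii <- 2 + 4 * runif(3)
    idx <- as.matrix(expand.grid(1:16, 1:16, 1:16))
    mask <- array(0L, c(16, 16, 16))
    inside <- rowSums(sweep(idx, 2, ctr)^2 / rep(radii^2, each = nrow(idx))) <= 1
    mask[idx[inside, , drop = FALSE]] <- 1L
    m <- extract_mesh(mask, c(1, 1, 1))
    expect_true(is_watertight(m))
    expect_length(mesh_components(m), 1L)
    expect_equal(euler_characteristic(m), 2)
  }
})

test_that("bilateral split orders halves by the first axis", {
  mk_ellipsoid <- function(center) {
    s <- icosphere(2, radius = 4)
    surface_mesh(sweep(s$vertices, 2, center, "+"), s$faces)
  }
  right <- mk_ellipsoid(c(-20, 0, 0))
  left <- mk_ellipsoid(c(20, 0, 0))
  fused <- surface_mesh(rbind(left$vertices, right$vertices),
                        rbind(left$faces, right$faces + n_vertices(left)))
  halves <- split_bilateral(fused)
  expect_lt(mean(halves$right$vertices[, 1]), 0)
  expect_gt(mean(halves$left$vertices[, 1]), 0)
  flipped <- split_bilateral(fused, right_is_negative = FALSE)
  expect_gt(mean(flipped$right$vertices[, 1]), 0)

  expect_error(split_bilateral(left), "expected 2 components, found 1")
  three <- surface_mesh(
    rbind(fused$vertices, sweep(left$vertices, 2, c(60, 0, 0), "+")),
    rbind(fused$faces, left$faces + n_vertices(fused)))
  expect_error(split_bilateral(three), "found 3")
})

test_that("decimation hits the vertex budget and preserves topology", {
  ico <- icosphere(4) # 2562 vertices, 5120 faces
  out <- decimate_smooth_center(ico, target_vertices = 1000)
  expect_gte(n_vertices(out), 980)
  expect_lte(n_vertices(out), 1020)
  expect_equal(euler_characteristic(out), 2)
  expect_true(is_watertight(out))
  expect_lt(sqrt(sum(colMeans(out$vertices)^2)), 1e-9 * bbox_diagonal(out))

  # already at target: pass-through with warning, count unchanged
  small <- icosphere(2)
  expect_warning(kept <- decimate_smooth_center(small, 1000), "skipping")
  expect_equal(n_vertices(kept), n_vertices(small))
})

test_that("Taubin smoothing is low-shrink on a sphere", {
  s <- icosphere(3)
  sm <- taubin_smooth(s, iterations = 10)
  r0 <- mean(sqrt(rowSums(s$vertices^2)))
  r1 <- mean(sqrt(rowSums(sm$vertices^2)))
  expect_lt(abs(r1 - r0) / r0, 0.01)
})

test_that("label volumes round-trip through NIfTI with spacing intact", {
  vox <- array(0L, c(6, 5, 4)); vox[2:4, 2:4, 2:3] <- 2L
  lv <- label_volume(vox, spacing = c(1.5, 2, 2.5),
                     organ_codes = c(thing = 2L))
  tf <- withr::local_tempfile(fileext = ".nii.gz")
  write_label_volume(lv, tf)
  back <- read_label_volume(tf, organ_codes = c(thing = 2L))
  expect_equal(back$voxels, lv$voxels, ignore_attr = TRUE)
  expect_equal(back$spacing, lv$spacing, tolerance = 1e-6)
  expect_equal(sum(organ_mask(back, "thing")), sum(vox == 2L))
  expect_error(organ_mask(back, "nope"), "unknown organ")
  expect_error(label_volume(vox, spacing = c(1, -1, 1)), "positive")
})

test_that("mesh IO round-trips PLY, OBJ and reads ASCII STL", {
  m <- icosphere(1, radius = 2.5)
  for (ext in c(".ply", ".obj")) {
    tf <- withr::local_tempfile(fileext = ext)
    write_mesh(m, tf)
    back <- read_mesh(tf)
    expect_equal(back$vertices, m$vertices, tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(back$faces, m$faces, ignore_attr = TRUE)
  }
  # minimal ASCII STL: one triangle, shared-vertex dedup
  tf <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid t", "facet normal 0 0 1", "outer loop",
               "vertex 0 0 0", "vertex 1 0 0", "vertex 0 1 0",
               "endloop", "endfacet", "endsolid t"), tf)
  st <- read_mesh(tf)
  expect_equal(n_vertices(st), 3L)
  expect_equal(n_faces(st), 1L)
})
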