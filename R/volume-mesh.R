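#' Organ-labelled voxel volume
#'
#' Container for a 3-D integer label image: per-voxel organ codes (0 =
#' background) plus the voxel spacing in mm. The third array dimension is
#' taken to be the axial (slice) direction, as in CT label volumes.
#'
#' @param voxels 3-D integer array of organ codes.
#' @param spacing numeric length-3, mm per voxel along each axis; strictly
#'   positive.
#' @param organ_codes optional named integer vector mapping organ name to
#'   code.
#' @return a `label_volume` object.
#' @export
label_volume <- function(voxels, spacing = c(1, 1, 1), organ_codes = NULL) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3-D array")
  if (any(voxels < 0) || any(voxels != round(voxels)))
    stop("organ codes must be non-negative integers")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values")
  if (!is.null(organ_codes)) {
    nms <- names(organ_codes)
    if (is.null(nms) && length(organ_codes))
      stop("organ_codes must be named")
    organ_codes <- stats::setNames(as.integer(organ_codes), nms)
  }
  structure(list(voxels = voxels, spacing = spacing,
                 organ_codes = organ_codes),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, spacing %s mm, codes: %s\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(setdiff(sort(unique(as.vector(x$voxels))), 0L),
                    collapse = ", ")))
  invisible(x)
}

#' Read a NIfTI-1 label volume
#'
#' Reads a `.nii`/`.nii.gz` segmentation image and wraps it as a
#' [label_volume()], taking the voxel spacing from the NIfTI header.
#'
#' @param path path to the NIfTI file.
#' @param organ_codes optional named integer vector of organ codes.
#' @return a `label_volume`.
#' @export
read_label_volume <- function(path, organ_codes = NULL) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  voxels <- array(as.integer(round(as.vector(img))), dim(img))
  label_volume(voxels, spacing = spacing, organ_codes = organ_codes)
}

#' Write a label volume as NIfTI-1
#'
#' @param volume a `label_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "label_volume"))
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Binary mask of one organ
#'
#' @param volume a `label_volume`.
#' @param organ organ name (looked up in `organ_codes`) or integer code.
#' @return 3-D 0/1 integer array.
#' @export
organ_mask <- function(volume, organ) {
  stopifnot(inherits(volume, "label_volume"))
  code <- if (is.character(organ)) {
    if (is.null(volume$organ_codes) || !organ %in% names(volume$organ_codes))
      stop("unknown organ name: ", organ)
    volume$organ_codes[[organ]]
  } else as.integer(organ)
  mask <- array(as.integer(volume$voxels == code), dim(volume$voxels))
  if (sum(mask) == 0L) stop("no voxels carry organ code ", code)
  mask
}

assert_binary_mask <- function(mask) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D array")
  if (is.logical(mask)) mask <- array(as.integer(mask), dim(mask))
  if (!all(mask %in% c(0L, 1L))) stop("mask must be binary (0/1)")
  storage.mode(mask) <- "integer"
  mask
}

#' Slice-wise morphological cleaning of a binary mask
#'
#' Processes every axial slice (third array index) independently:
#' morphological opening with a 5x5 box kernel, closing with the same kernel,
#' then filling of background regions fully enclosed by foreground. Opening
#' removes speckle smaller than the kernel; closing bridges small gaps; the
#' fill removes interior structures such as vessels or airways from an organ
#' mask.
#'
#' @param mask 3-D binary (0/1) array.
#' @param kernel_size odd box-kernel side length, default 5.
#' @return cleaned binary array of the same shape.
#' @export
clean_mask_slices <- function(mask, kernel_size = 5) {
  mask <- assert_binary_mask(mask)
  kern <- EBImage::makeBrush(kernel_size, shape = "box")
  out <- mask
  for (k in seq_len(dim(mask)[3])) {
    sl <- mask[, , k]
    if (!any(sl == 1L)) next
    sl <- EBImage::opening(sl, kern)
    sl <- EBImage::closing(sl, kern)
    sl <- EBImage::fillHull(sl)
    out[, , k] <- as.integer(sl > 0)
  }
  out
}

#' Extract the outer surface mesh of a binary mask
#'
#' Runs isosurface extraction at level 0.5 on the binary field (marching
#' tetrahedra on the zero-padded grid), scales vertices by the voxel spacing
#' and keeps only the connected surface component with the largest face
#' count.
#'
#' @param mask 3-D binary array.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param largest_only keep only the largest surface component (default).
#'   Set `FALSE` for paired organs whose two halves are split afterwards
#'   with [split_bilateral()].
#' @return a watertight `surface_mesh` (single component unless
#'   `largest_only = FALSE`).
#' @export
extract_mesh <- function(mask, spacing = c(1, 1, 1), largest_only = TRUE) {
  mask <- assert_binary_mask(mask)
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  if (sum(mask) == 0L) stop("empty organ mask")
  d <- dim(mask)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask == 1L
  raw <- .cpp_marching_tets(as.logical(padded), dim(padded), spacing)
  verts <- sweep(raw$vertices, 2, spacing) # undo the one-voxel zero pad
  mesh <- surface_mesh(verts, raw$faces)
  if (!largest_only) return(mesh)
  comps <- mesh_components(mesh)
  comps[[1]]
}

#' Split a two-component mesh into bilateral halves
#'
#' For paired organs (lungs, kidneys) whose mask yields exactly two connected
#' surface components. Sides are assigned from the component centroid along
#' the chosen axis; under the radiological convention the smaller coordinate
#' is the subject's right.
#'
#' @param mesh a `surface_mesh` with exactly two connected components.
#' @param axis axis used to order the halves (1 = first volume axis).
#' @param right_is_negative logical; `TRUE` (radiological convention) labels
#'   the smaller-coordinate component "right".
#' @return named list with elements `right` and `left`.
#' @export
split_bilateral <- function(mesh, axis = 1, right_is_negative = TRUE) {
  comps <- mesh_components(mesh)
  if (length(comps) != 2L)
    stop(sprintf("expected 2 components, found %d", length(comps)))
  centr <- vapply(comps, function(m) mean(m$vertices[, axis]), numeric(1))
  ord <- order(centr) # smaller coordinate first
  halves <- comps[ord]
  if (right_is_negative) {
    list(right = halves[[1]], left = halves[[2]])
  } else {
    list(right = halves[[2]], left = halves[[1]])
  }
}

#' Taubin mesh smoothing
#'
#' Alternating lambda/mu passes of the umbrella (uniform Laplacian) operator.
#' The negative mu step compensates the shrinkage of plain Laplacian
#' smoothing, so smoothing a sphere changes its radius by well under 1%.
#'
#' @param mesh a `surface_mesh`.
#' @param iterations number of lambda+mu passes.
#' @param lambda positive smoothing step.
#' @param mu negative inflation step, `|mu| > lambda`.
#' @return smoothed `surface_mesh`.
#' @export
taubin_smooth <- function(mesh, iterations = 10, lambda = 0.5, mu = -0.53) {
  e <- unique(mesh_edges(mesh))
  V <- n_vertices(mesh)
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(V, V))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  x <- mesh$vertices
  for (it in seq_len(iterations)) {
    x <- x + lambda * (as.matrix(A %*% x) / deg - x)
    x <- x + mu * (as.matrix(A %*% x) / deg - x)
  }
  surface_mesh(x, mesh$faces)
}

#' Decimate, smooth and center a mesh
#'
#' The standard pre-registration conditioning step: quadric edge-collapse
#' decimation to a common vertex budget, Taubin smoothing, and translation of
#' the vertex centroid to the origin. Meshes already at or below the target
#' count are passed through (no upsampling) with a warning.
#'
#' @param mesh a `surface_mesh`.
#' @param target_vertices vertex budget after decimation (default 1000).
#' @param taubin_iters smoothing passes (default 10).
#' @param lambda,mu Taubin parameters.
#' @return processed `surface_mesh`, centroid at the origin.
#' @export
decimate_smooth_center <- function(mesh, target_vertices = 1000,
                                   taubin_iters = 10,
                                   lambda = 0.5, mu = -0.53) {
  if (n_vertices(mesh) < target_vertices) {
    warning(sprintf("mesh has %d < %d vertices; skipping decimation",
                    n_vertices(mesh), target_vertices))
  } else if (n_vertices(mesh) > target_vertices) {
    dec <- .cpp_decimate_quadric(mesh$vertices, mesh$faces,
                                 as.integer(target_vertices))
    mesh <- surface_mesh(dec$vertices, dec$faces)
    if (abs(n_vertices(mesh) - target_vertices) > 0.02 * target_vertices)
      warning(sprintf("decimation stopped at %d vertices (target %d)",
                      n_vertices(mesh), target_vertices))
  }
  if (taubin_iters > 0)
    mesh <- taubin_smooth(mesh, taubin_iters, lambda, mu)
  center_mesh(mesh)
}

#' Translate a mesh so its vertex centroid is at the origin
#' @param mesh a `surface_mesh`.
#' @return centered `surface_mesh`.
#' @export
center_mesh <- function(mesh) {
  surface_mesh(sweep(mesh$vertices, 2, colMeans(mesh$vertices)), mesh$faces)
}

#' Mirror a mesh along one axis
#'
#' Orientation fixing is a per-dataset configuration choice (no automatic
#' heuristic): flips the given coordinate and swaps a face column so the
#' winding orientation is preserved.
#'
#' @param mesh a `surface_mesh`.
#' @param axis 1, 2 or 3.
#' @return flipped `surface_mesh`.
#' @export
flip_mesh_axis <- function(mesh, axis) {
  stopifnot(axis %in% 1:3)
  v <- mesh$vertices
  v[, axis] <- -v[, axis]
  surface_mesh(v, mesh$faces[, c(1, 3, 2)])
}
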