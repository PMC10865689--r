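#' Triangle surface mesh
#'
#' Lightweight container for a triangle mesh in millimetre coordinates: a
#' numeric `V x 3` vertex matrix and an integer `F x 3` face matrix of
#' 1-based vertex indices. This is the unit of registration and feature
#' extraction throughout the package.
#'
#' @param vertices numeric matrix, `V x 3`, vertex coordinates in mm.
#' @param faces integer matrix, `F x 3`, 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range [1, V]")
  structure(list(vertices = vertices, faces = faces),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' @export
format.surface_mesh <- function(x, ...) {
  sprintf("<surface_mesh: %d vertices, %d faces>",
          nrow(x$vertices), nrow(x$faces))
}

#' Number of vertices / faces of a mesh
#' @param mesh a `surface_mesh`.
#' @return integer count.
#' @export
n_vertices <- function(mesh) nrow(mesh$vertices)

#' @rdname n_vertices
#' @export
n_faces <- function(mesh) nrow(mesh$faces)

face_corner <- function(mesh, k) mesh$vertices[mesh$faces[, k], , drop = FALSE]

#' Enclosed volume of a watertight mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra against
#' the origin). The absolute value is returned, so the result does not depend
#' on whether the winding points inward or outward.
#'
#' @param mesh a `surface_mesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); cc <- face_corner(mesh, 3)
  cross <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
                 b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
                 b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  abs(sum(a * cross)) / 6
}

signed_mesh_volume <- function(mesh) {
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); cc <- face_corner(mesh, 3)
  cross <- cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
                 b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
                 b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
  sum(a * cross) / 6
}

#' Total surface area of a mesh
#' @param mesh a `surface_mesh`.
#' @return area in mm^2.
#' @export
mesh_area <- function(mesh) {
  sum(triangle_areas(mesh))
}

triangle_areas <- function(mesh) {
  a <- face_corner(mesh, 1)
  u <- face_corner(mesh, 2) - a
  w <- face_corner(mesh, 3) - a
  cross <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                 u[, 3] * w[, 1] - u[, 1] * w[, 3],
                 u[, 1] * w[, 2] - u[, 2] * w[, 1])
  0.5 * sqrt(rowSums(cross^2))
}

face_normals <- function(mesh, normalize = TRUE) {
  a <- face_corner(mesh, 1)
  u <- face_corner(mesh, 2) - a
  w <- face_corner(mesh, 3) - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  if (normalize) {
    len <- sqrt(rowSums(n^2))
    len[len == 0] <- 1
    n <- n / len
  }
  n
}

#' Outward unit vertex normals
#'
#' Area-weighted average of incident face normals, flipped globally so they
#' point away from the enclosed volume (the face winding itself may be either
#' orientation).
#'
#' @param mesh a watertight `surface_mesh`.
#' @return `V x 3` matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh, normalize = FALSE) # length 2*area: area weighting
  vn <- matrix(0, n_vertices(mesh), 3)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    for (d in 1:3)
      vn[, d] <- vn[, d] + tapply_add(fn[, d], idx, n_vertices(mesh))
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn <- vn / len
  if (signed_mesh_volume(mesh) < 0) vn <- -vn
  vn
}

tapply_add <- function(values, index, n) {
  out <- numeric(n)
  agg <- rowsum(values, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Connected components of a mesh
#'
#' Splits a mesh into its vertex-connected components, each returned as a
#' standalone `surface_mesh` with faces re-indexed.
#'
#' @param mesh a `surface_mesh`.
#' @return list of `surface_mesh`, ordered by decreasing face count.
#' @export
mesh_components <- function(mesh) {
  e <- unique(mesh_edges(mesh))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_vertices(mesh) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  face_comp <- comp[mesh$faces[, 1]]
  keep_ids <- order(-tabulate(face_comp, nbins = max(comp)))
  out <- list()
  for (cid in keep_ids) {
    fsel <- mesh$faces[face_comp == cid, , drop = FALSE]
    if (nrow(fsel) == 0L) next
    vids <- sort(unique(as.vector(fsel)))
    remap <- integer(n_vertices(mesh))
    remap[vids] <- seq_along(vids)
    out[[length(out) + 1L]] <- surface_mesh(
      mesh$vertices[vids, , drop = FALSE],
      matrix(remap[fsel], ncol = 3))
  }
  out
}

#' Watertightness and Euler characteristic
#'
#' A mesh is watertight when every edge is shared by exactly two faces.
#'
#' @param mesh a `surface_mesh`.
#' @return `is_watertight()`: logical. `euler_characteristic()`: integer
#'   `V - E + F` (2 for a genus-0 closed surface).
#' @export
is_watertight <- function(mesh) {
  e <- mesh_edges(mesh)
  key <- paste(e[, 1], e[, 2])
  all(table(key) == 2L)
}

#' @rdname is_watertight
#' @export
euler_characteristic <- function(mesh) {
  n_vertices(mesh) - nrow(unique(mesh_edges(mesh))) + n_faces(mesh)
}

#' Bounding-box diagonal of a mesh or point set
#' @param x a `surface_mesh` or numeric matrix of points.
#' @return scalar length.
#' @export
bbox_diagonal <- function(x) {
  pts <- if (inherits(x, "surface_mesh")) x$vertices else as.matrix(x)
  sqrt(sum((apply(pts, 2, max) - apply(pts, 2, min))^2))
}

#' Subdivided icosahedron sphere
#'
#' Deterministic genus-0 triangulation of the sphere used by the synthetic
#' cohort generator and the geometry calibration tests. Vertex counts by
#' subdivision level: 12, 42, 162, 642, 2562, ...
#'
#' @param subdivisions non-negative integer, number of 4-to-1 face splits.
#' @param radius sphere radius (mm).
#' @return a `surface_mesh` with outward-wound faces.
#' @export
icosphere <- function(subdivisions = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mids <- new.env(parent = emptyenv())
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      k <- edge_key(a, b)
      if (!is.null(mids[[k]])) return(mids[[k]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      newv[[length(newv) + 1L]] <<- m
      id <- nv + length(newv)
      mids[[k]] <- id
      id
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(i - 1L) * 4L + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  surface_mesh(v * radius, f)
}

#' Read and write triangle meshes
#'
#' Plain-text mesh IO: ASCII PLY, Wavefront OBJ and ASCII STL, chosen by file
#' extension. `write_mesh()` emits ASCII PLY or OBJ.
#'
#' @param path file path ending in `.ply`, `.obj` or `.stl`.
#' @param mesh a `surface_mesh` (for writing).
#' @return `read_mesh()` returns a `surface_mesh`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = read_ply(path),
         obj = read_obj(path),
         stl = read_stl_ascii(path),
         stop("unsupported mesh format: .", ext))
}

#' @rdname read_mesh
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = write_ply(mesh, path),
         obj = write_obj(mesh, path),
         stop("unsupported mesh output format: .", ext))
  invisible(path)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", n_vertices(mesh)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", n_faces(mesh)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), con)
  writeLines(paste(3, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
}

read_ply <- function(path) {
  lines <- readLines(path)
  if (!grepl("^ply", lines[1])) stop("not a PLY file")
  hdr_end <- which(lines == "end_header")[1]
  hdr <- lines[seq_len(hdr_end)]
  if (!any(grepl("format ascii", hdr)))
    stop("only ASCII PLY is supported")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
  body <- lines[(hdr_end + 1L):length(lines)]
  vl <- body[seq_len(nv)]
  fl <- body[nv + seq_len(nf)]
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    x <- as.integer(x)
    if (x[1] != 3L) stop("only triangle faces are supported")
    x[2:4] + 1L
  }))
  surface_mesh(v, f)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("v", mesh$vertices[, 1], mesh$vertices[, 2],
                   mesh$vertices[, 3]), con)
  writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
}

read_obj <- function(path) {
  lines <- readLines(path)
  vl <- grep("^v ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) as.numeric(x[x != ""][1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                             function(x) {
    x <- x[x != ""]
    as.integer(sub("/.*", "", x))[1:3]
  }))
  surface_mesh(v, f)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path)
  if (!grepl("^\\s*solid", lines[1]))
    stop("only ASCII STL is supported")
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                  function(x) as.numeric(x[2:4])))
  if (nrow(coords) %% 3 != 0) stop("malformed STL: vertex count not a multiple of 3")
  key <- apply(coords, 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  vid <- match(key, key[uniq])
  v <- coords[uniq, , drop = FALSE]
  f <- matrix(vid, ncol = 3, byrow = TRUE)
  surface_mesh(v, f)
}
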