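#' Tukey halfspace depth of a point
#'
#' Exact halfspace (location) depth in 2-D: the minimum, over all closed
#' halfplanes whose boundary passes through `p`, of the number of data points
#' inside the halfplane. Computed by an angular sweep over the critical
#' directions defined by the data, so the result is exact, not approximate.
#'
#' @param p numeric length-2 query point.
#' @param points `n x 2` data matrix.
#' @return integer depth in `[0, n]`.
#' @export
halfspace_depth <- function(p, points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 1)
  v <- sweep(points, 2, as.numeric(p))
  r2 <- rowSums(v^2)
  n_coincident <- sum(r2 < 1e-24)
  v <- v[r2 >= 1e-24, , drop = FALSE]
  m <- nrow(v)
  if (m == 0) return(n_coincident)
  ang <- atan2(v[, 2], v[, 1])
  # count(theta) = #{i : angle(a_i, theta) <= pi/2} is piecewise constant
  # with breakpoints at a_i +- pi/2; check every breakpoint and midpoint
  brk <- sort(unique(c(ang + pi / 2, ang - pi / 2) %% (2 * pi)))
  mids <- (brk + c(brk[-1], brk[1] + 2 * pi)) / 2
  cand <- c(brk, mids %% (2 * pi))
  counts <- vapply(cand, function(th) sum(cos(ang - th) >= -1e-12),
                   integer(1))
  min(counts) + n_coincident
}

halfspace_depths <- function(points) {
  points <- as.matrix(points)
  vapply(seq_len(nrow(points)),
         function(i) halfspace_depth(points[i, ], points), integer(1))
}

# Directed-line constraints for the depth regions: for every ordered pair of
# distinct data points, the halfplane u.x <= c bounded by their line, with
# `outside` the number of points strictly beyond it. The depth region
# D_k = {x : depth(x) >= k} is the intersection of all such halfplanes with
# outside <= k - 1 (plus any with outside = 0, which bound the convex hull,
# so D_k is bounded for every k >= 1).
depth_constraints <- function(pts) {
  n <- nrow(pts)
  scale <- sqrt(mean(rowSums(sweep(pts, 2, colMeans(pts))^2))) + 1e-300
  tol <- 1e-9 * scale
  U <- NULL; cc <- NULL; cnt <- NULL
  for (i in seq_len(n)) {
    e <- sweep(pts, 2, pts[i, ])          # p_j - p_i
    len <- sqrt(rowSums(e^2))
    keep <- len > tol
    if (!any(keep)) next
    u <- cbind(e[keep, 2], -e[keep, 1]) / len[keep]
    ci <- as.vector(u %*% pts[i, ])
    proj <- u %*% t(pts)                  # m x n
    outside <- rowSums(proj > ci + tol)
    U <- rbind(U, u); cc <- c(cc, ci); cnt <- c(cnt, outside)
  }
  list(U = U, c = cc, cnt = cnt, tol = tol)
}

clip_halfplane <- function(poly, u, cval, tol) {
  # Sutherland-Hodgman clip of polygon against u.x <= cval
  if (is.null(poly) || nrow(poly) == 0) return(poly)
  d <- as.vector(poly %*% u) - cval
  inside <- d <= tol
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  m <- nrow(poly)
  out <- matrix(numeric(0), 0, 2)
  for (a in seq_len(m)) {
    b <- a %% m + 1
    if (inside[a]) out <- rbind(out, poly[a, ])
    if (inside[a] != inside[b]) {
      t <- d[a] / (d[a] - d[b])
      out <- rbind(out, poly[a, ] + t * (poly[b, ] - poly[a, ]))
    }
  }
  out
}

# exact Tukey depth region D_k as a convex polygon (possibly degenerate)
depth_region <- function(cons, pts, k) {
  sel <- which(cons$cnt <= k - 1)
  lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
  pad <- max(hi - lo) + 1
  poly <- rbind(c(lo[1] - pad, lo[2] - pad), c(hi[1] + pad, lo[2] - pad),
                c(hi[1] + pad, hi[2] + pad), c(lo[1] - pad, hi[2] + pad))
  for (s in sel) {
    poly <- clip_halfplane(poly, cons$U[s, ], cons$c[s], cons$tol)
    if (nrow(poly) == 0) break
  }
  poly
}

polygon_area_centroid <- function(poly) {
  if (nrow(poly) < 3) return(colMeans(poly))
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12 * (diff(range(x)) * diff(range(y)) + 1e-300))
    return(colMeans(poly))
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

# radial extent of a star-shaped polygon around an interior point
polygon_radius <- function(poly, center, angles) {
  if (is.null(poly) || nrow(poly) < 3) return(rep(0, length(angles)))
  p <- sweep(poly, 2, center)
  m <- nrow(p)
  nxt <- c(2:m, 1)
  out <- numeric(length(angles))
  for (qi in seq_along(angles)) {
    d <- c(cos(angles[qi]), sin(angles[qi]))
    rbest <- 0
    for (ei in seq_len(m)) {
      a <- p[ei, ]; b <- p[nxt[ei], ]
      e <- b - a
      den <- -d[1] * e[2] + d[2] * e[1]
      if (abs(den) < 1e-14) next
      tt <- (-a[1] * e[2] + a[2] * e[1]) / den
      ss <- (d[1] * a[2] - d[2] * a[1]) / den
      if (tt >= 0 && ss >= -1e-9 && ss <= 1 + 1e-9) rbest <- max(rbest, tt)
    }
    out[qi] <- rbest
  }
  out
}

#' Bagplot of a 2-D point cloud
#'
#' The two-dimensional boxplot analogue built on Tukey halfspace depth: the
#' depth median (centroid of the maximal-depth region), a convex "bag"
#' holding the deepest 50% of the points, and a "fence" obtained by
#' inflating the bag by `fence_factor` about the depth median. Points beyond
#' the fence are outliers.
#'
#' The bag interpolates between the tightest depth contour holding at least
#' `floor(n/2)` points and the next-deeper contour. Because every point of
#' depth k lies exactly on the contour of its own depth region, the points
#' of the boundary depth level are admitted in order of distance to the
#' depth median until the bag holds exactly `floor(n/2)` points (boundary
#' points count as inside); the bag polygon is the convex hull of the
#' admitted points. This keeps the published 50% coverage exact for points
#' in general position.
#'
#' @param points `n x 2` numeric matrix or data frame (n >= 5, not all
#'   collinear).
#' @param fence_factor bag inflation factor rho (classic default 3).
#' @return an object of class `bagplot`: `depth_median`, `bag_polygon`,
#'   `fence_polygon`, `depths`, `regions` (factor with levels bag, fence,
#'   outlier).
#' @export
compute_bagplot <- function(points, fence_factor = 3) {
  pts <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 5) stop("bagplot needs at least 5 points")
  if (qr(sweep(pts, 2, colMeans(pts)))$rank < 2)
    stop("points are collinear; jitter the coordinates first")
  depths <- halfspace_depths(pts)
  kmax <- max(depths)
  cons <- depth_constraints(pts)
  med_region <- depth_region(cons, pts, kmax)
  depth_median <- if (nrow(med_region) >= 1) {
    polygon_area_centroid(med_region)
  } else {
    colMeans(pts[depths == kmax, , drop = FALSE])
  }
  half <- floor(n / 2)
  sizes <- vapply(seq_len(kmax), function(k) sum(depths >= k), integer(1))
  kstar <- max(which(sizes >= half))
  inner_idx <- which(depths >= kstar + 1)
  cand_idx <- which(depths == kstar)
  need <- half - length(inner_idx)
  if (need > 0) {
    # admit boundary-level points nearest the depth median (ties: index)
    r_c <- sqrt(rowSums(sweep(pts[cand_idx, , drop = FALSE], 2,
                              depth_median)^2))
    admit <- cand_idx[order(r_c, cand_idx)][seq_len(need)]
  } else admit <- integer(0)
  bag_pts <- pts[c(inner_idx, admit), , drop = FALSE]
  bag <- bag_pts[grDevices::chull(bag_pts), , drop = FALSE]
  fence <- sweep(sweep(bag, 2, depth_median) * fence_factor, 2,
                 depth_median, "+")
  bp <- structure(list(depth_median = depth_median,
                       bag_polygon = bag,
                       fence_polygon = fence,
                       fence_factor = fence_factor,
                       depths = depths,
                       points = pts),
                  class = "bagplot")
  bp$regions <- classify_regions(bp)
  bp
}

#' Classify points into bagplot regions
#'
#' Assigns each point exactly one label: `bag` if inside (or on) the bag
#' polygon, else `fence` if inside the fence polygon, else `outlier`.
#' Membership is tested radially about the depth median, which is exact for
#' the star-shaped bag and fence polygons.
#'
#' @param bp a `bagplot`.
#' @param points optional `n x 2` matrix; defaults to the points the bagplot
#'   was computed from.
#' @return factor with levels `bag`, `fence`, `outlier`.
#' @export
classify_regions <- function(bp, points = NULL) {
  stopifnot(inherits(bp, "bagplot"))
  pts <- if (is.null(points)) bp$points else as.matrix(points)
  c0 <- bp$depth_median
  dv <- sweep(pts, 2, c0)
  r <- sqrt(rowSums(dv^2))
  ang <- atan2(dv[, 2], dv[, 1])
  rb <- polygon_radius(bp$bag_polygon, c0, ang)
  rf <- polygon_radius(bp$fence_polygon, c0, ang)
  eps <- 1e-9 * (max(r) + 1)
  lab <- ifelse(r <= rb + eps, "bag",
                ifelse(r <= rf + eps, "fence", "outlier"))
  factor(lab, levels = c("bag", "fence", "outlier"))
}

#' @export
print.bagplot <- function(x, ...) {
  tab <- table(x$regions)
  cat(sprintf("<bagplot> n = %d: %d bag, %d fence, %d outlier; depth median (%.3g, %.3g)\n",
              length(x$depths), tab[["bag"]], tab[["fence"]],
              tab[["outlier"]], x$depth_median[1], x$depth_median[2]))
  invisible(x)
}

#' @export
tidy.bagplot <- function(x, ...) {
  tibble::tibble(dim1 = x$points[, 1], dim2 = x$points[, 2],
                 depth = x$depths, region = x$regions)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a bagplot
#'
#' @param object a `bagplot`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bagplot <- function(object, ...) {
  poly <- function(m) tibble::tibble(dim1 = m[, 1], dim2 = m[, 2])
  dat <- tidy.bagplot(object)
  ggplot2::ggplot() +
    ggplot2::geom_polygon(data = poly(object$fence_polygon),
                          ggplot2::aes(.data$dim1, .data$dim2),
                          fill = "grey85") +
    ggplot2::geom_polygon(data = poly(object$bag_polygon),
                          ggplot2::aes(.data$dim1, .data$dim2),
                          fill = "grey60") +
    ggplot2::geom_point(data = dat,
                        ggplot2::aes(.data$dim1, .data$dim2,
                                     colour = .data$region)) +
    ggplot2::annotate("point", x = object$depth_median[1],
                      y = object$depth_median[2], shape = 3, size = 3) +
    ggplot2::theme_minimal()
}
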