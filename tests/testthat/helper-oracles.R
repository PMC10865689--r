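# Independent brute-force oracles used across the suite.

# O(n^3)-flavoured halfspace depth: scan halfplanes whose boundary passes
# through p, with normals drawn from every data-point direction (the critical
# set), their perpendiculars, and small rotations either side.
brute_depth <- function(p, pts) {
  v <- sweep(pts, 2, as.numeric(p))
  keep <- rowSums(v^2) > 1e-24
  coincident <- sum(!keep)
  v <- v[keep, , drop = FALSE]
  if (nrow(v) == 0) return(coincident)
  eps <- 1e-7
  rot <- function(a, th) cbind(a[, 1] * cos(th) - a[, 2] * sin(th),
                               a[, 1] * sin(th) + a[, 2] * cos(th))
  normals <- rbind(v, -v,
                   cbind(v[, 2], -v[, 1]), cbind(-v[, 2], v[, 1]),
                   rot(cbind(v[, 2], -v[, 1]), eps),
                   rot(cbind(v[, 2], -v[, 1]), -eps),
                   rot(cbind(-v[, 2], v[, 1]), eps),
                   rot(cbind(-v[, 2], v[, 1]), -eps))
  counts <- apply(normals, 1, function(nrm) sum(v %*% nrm >= -1e-12))
  min(counts) + coincident
}

# all permutations of 1..n (n <= 7 in the tests)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1))
    for (pos in 0:(n - 1))
      out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

brute_assignment_cost <- function(cm) {
  n <- nrow(cm)
  min(vapply(all_perms(n),
             function(p) sum(cm[cbind(seq_len(n), p)]), numeric(1)))
}

# exhaustive two-sided Mann-Whitney p over all subsets of the pooled sample
enum_mwu_p <- function(x, y) {
  m <- length(x)
  r <- rank(c(x, y))
  mu <- m * (length(r) + 1) / 2
  w_obs <- sum(r[seq_len(m)])
  subsets <- utils::combn(length(r), m)
  ws <- apply(subsets, 2, function(ix) sum(r[ix]))
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# sphere-like test meshes
unit_cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
    c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
    c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  surface_mesh(v, f)
}

small_feature_blocks <- function(n = 10, dims = c(14, 11, 9), seed = 3) {
  blocks <- morphomcia:::with_seed(seed, lapply(dims, function(d)
    standardize_features(feature_matrix(matrix(stats::rnorm(d * n), d, n)))))
  names(blocks) <- paste0("block", seq_along(blocks))
  blocks
}
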