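#' Per-individual location-robustness count
#'
#' Given the bagplot region of every organ of every individual (one
#' projection method), counts for each individual the maximum number of
#' organs assigned to the same region. With S organs the count lies in
#' `[ceiling(S/3), S]`; high counts mean the organs agree on where the
#' individual sits in the population.
#'
#' @param regions long tibble with columns `individual`, `organ`, `region`
#'   (values bag / fence / outlier); complete, one row per individual-organ.
#' @return tibble with columns `individual`, `count`.
#' @export
max_same_region_count <- function(regions) {
  stopifnot(all(c("individual", "organ", "region") %in% names(regions)))
  if (anyNA(regions$region)) stop("region table has missing entries")
  tab <- dplyr::count(regions, .data$individual, .data$organ)
  if (any(tab$n != 1L))
    stop("region table must have exactly one row per individual and organ")
  n_org <- length(unique(regions$organ))
  per_ind <- dplyr::count(regions, .data$individual)
  if (any(per_ind$n != n_org))
    stop("region table has missing entries (incomplete organ sets)")
  regions |>
    dplyr::count(.data$individual, .data$region) |>
    dplyr::group_by(.data$individual) |>
    dplyr::summarise(count = max(.data$n), .groups = "drop")
}

#' Exact tie-aware two-sided Mann-Whitney U test
#'
#' Permutation-exact p-value for the two-sample rank-sum statistic, valid
#' with ties: the null distribution of the group-1 rank sum (midranks) over
#' all subsets of the pooled sample is computed by a shift-algorithm dynamic
#' program. Used for group sizes up to 20 each; larger groups fall back to
#' the normal approximation with tie correction.
#'
#' @param x,y numeric vectors.
#' @param exact_max largest per-group size for the exact computation.
#' @return list with `U` (group-1 U statistic), `p` (two-sided), `method`.
#' @export
mwu_test <- function(x, y, exact_max = 20) {
  m <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(m)])
  u_obs <- w_obs - m * (m + 1) / 2
  if (m <= exact_max && n2 <= exact_max) {
    # distribution of the group-1 rank sum over all C(N, m) subsets;
    # doubled midranks are integers, so index by integer sums
    r2 <- as.integer(round(2 * r))
    maxs <- sum(sort(r2, decreasing = TRUE)[seq_len(m)])
    # dp[[j]][s + 1] = number of j-subsets with doubled rank sum s
    dp <- vector("list", m + 1)
    dp[[1]] <- c(1, numeric(maxs))
    for (j in seq_len(m)) dp[[j + 1]] <- numeric(maxs + 1)
    for (item in r2) {
      for (j in rev(seq_len(m))) {
        shifted <- c(numeric(item), dp[[j]][seq_len(maxs + 1 - item)])
        dp[[j + 1]] <- dp[[j + 1]] + shifted
      }
    }
    counts <- dp[[m + 1]]
    sums <- (seq_along(counts) - 1) / 2
    mu_w <- m * (m + n2 + 1) / 2
    p <- sum(counts[abs(sums - mu_w) >= abs(w_obs - mu_w) - 1e-9]) /
      choose(m + n2, m)
    list(U = u_obs, p = min(1, p), method = "exact (shift algorithm)")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE))
    list(U = u_obs, p = wt$p.value, method = "normal approximation")
  }
}

#' Compare location-robustness across projection methods
#'
#' Kruskal-Wallis test (tie-corrected) of the per-individual robustness
#' counts across all methods, followed by all pairwise two-sided
#' Mann-Whitney U tests ([mwu_test()]; exact for group sizes up to 20).
#' Holm-adjusted pairwise p-values are reported alongside the raw ones.
#'
#' @param counts named list of equal-length integer vectors (one per
#'   method), or a tibble with columns `method` and `count`.
#' @return object of class `robustness_comparison`: `kruskal` (tibble) and
#'   `pairwise` (tibble with U, p, p_holm per method pair).
#' @export
compare_methods <- function(counts) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("method", "count") %in% names(counts)))
    counts <- split(counts$count, counts$method)
  }
  if (length(counts) < 2) stop("need at least 2 methods to compare")
  sizes <- lengths(counts)
  if (length(unique(sizes)) != 1L)
    stop("methods must cover the same cohort (equal vector lengths)")
  if (length(unique(unlist(counts))) == 1L) {
    kw <- tibble::tibble(statistic = 0, df = length(counts) - 1, p = 1)
  } else {
    k <- stats::kruskal.test(counts)
    kw <- tibble::tibble(statistic = unname(k$statistic),
                         df = unname(k$parameter), p = k$p.value)
  }
  pairs <- utils::combn(names(counts), 2, simplify = FALSE)
  pw <- purrr::map_dfr(pairs, function(pr) {
    t <- mwu_test(counts[[pr[1]]], counts[[pr[2]]])
    tibble::tibble(method1 = pr[1], method2 = pr[2],
                   U = t$U, p = t$p, method = t$method)
  })
  pw$p_holm <- stats::p.adjust(pw$p, method = "holm")
  structure(list(kruskal = kw, pairwise = pw,
                 counts = counts), class = "robustness_comparison")
}

#' @export
print.robustness_comparison <- function(x, ...) {
  cat(sprintf("<robustness_comparison> %d methods, n = %d per method\n",
              length(x$counts), length(x$counts[[1]])))
  cat(sprintf("Kruskal-Wallis H = %.3f (df = %d), p = %.4g\n",
              x$kruskal$statistic, x$kruskal$df, x$kruskal$p))
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.robustness_comparison <- function(x, ...) x$pairwise

#' @export
glance.robustness_comparison <- function(x, ...) x$kruskal
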