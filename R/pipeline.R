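#' Pipeline configuration
#'
#' Single configuration object for the end-to-end analysis: input mode,
#' per-stage parameters (all defaulting to the module defaults) and an
#' optional output directory. Every source of randomness (landmark
#' sampling, t-SNE initialization, simulation) is a named seed here, so
#' re-running a config reproduces its outputs byte for byte.
#'
#' @param mode `"simulate"` (generate a synthetic cohort), `"meshes"` (read
#'   per-organ mesh files) or `"features"` (read per-organ feature CSVs,
#'   skipping all geometry stages).
#' @param cohort a [cohort_spec()] (simulate mode).
#' @param mesh_files named list: organ -> character vector of mesh paths
#'   (meshes mode; names become individual IDs via file names).
#' @param feature_files named character vector: organ -> feature CSV path
#'   (features mode).
#' @param correspondence `"register"` runs CPD + Hungarian correspondence
#'   per organ; `"byindex"` trusts the existing vertex order (valid for the
#'   simulated cohort, whose meshes share one triangulation).
#' @param target_vertices decimation budget for meshes mode.
#' @param n_pairs,pairs_seed landmark-pair sampling; one pair set is drawn
#'   and reused for every organ, so features align across organs.
#' @param methods projection methods to run (subset of mcia, pca, tsne).
#' @param n_axes MCIA/PCA axes (2 for the bagplot stage).
#' @param block_scaling MCIA block pre-scaling (see [mcia_fit()]).
#' @param tsne_seed,tsne_iters,tsne_perplexity t-SNE parameters (perplexity
#'   `NULL` = feasibility default).
#' @param fence_factor bagplot fence inflation.
#' @param flip_axis optional axis (1-3) mirrored on every input mesh, the
#'   per-dataset orientation flag.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("simulate", "meshes", "features"),
                            cohort = cohort_spec(),
                            mesh_files = NULL,
                            feature_files = NULL,
                            correspondence = NULL,
                            target_vertices = 1000,
                            n_pairs = 500, pairs_seed = 42,
                            methods = c("mcia", "pca", "tsne"),
                            n_axes = 2,
                            block_scaling = "unit_inertia",
                            tsne_seed = 0, tsne_iters = 1000,
                            tsne_perplexity = NULL,
                            fence_factor = 3,
                            flip_axis = NULL,
                            out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.null(correspondence))
    correspondence <- if (mode == "simulate") "byindex" else "register"
  correspondence <- match.arg(correspondence, c("byindex", "register"))
  methods <- match.arg(methods, c("mcia", "pca", "tsne"), several.ok = TRUE)
  structure(list(mode = mode, cohort = cohort, mesh_files = mesh_files,
                 feature_files = feature_files,
                 correspondence = correspondence,
                 target_vertices = target_vertices,
                 n_pairs = n_pairs, pairs_seed = pairs_seed,
                 methods = methods, n_axes = n_axes,
                 block_scaling = block_scaling,
                 tsne_seed = tsne_seed, tsne_iters = tsne_iters,
                 tsne_perplexity = tsne_perplexity,
                 fence_factor = fence_factor,
                 flip_axis = flip_axis, out_dir = out_dir),
            class = "pipeline_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full multi-organ shape pipeline
#'
#' Executes mesh acquisition, (optional) registration, feature extraction,
#' the configured projections (MCIA jointly over organs; PCA and t-SNE per
#' organ), per-organ bagplots in each projection, and the per-individual
#' location-robustness comparison across methods. For MCIA, the bagplot of
#' an organ is computed on that organ's block scores within the shared
#' space.
#'
#' @param cfg a [pipeline_config()].
#' @return a `morphomcia_run`: list with `features` (standardized blocks),
#'   `embeddings` (method -> organ -> `embedding_2d`), `mcia` (fit or NULL),
#'   `center_distances`, `regions` (long tibble with method column),
#'   `robustness` (counts tibble), `comparison`
#'   (`robustness_comparison` or NULL), `truth` (simulate mode), `config`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  truth <- NULL
  meshes <- with_stage("input", switch(cfg$mode,
    simulate = {
      sim <- generate_cohort(cfg$cohort)
      truth <- sim$truth
      sim$meshes
    },
    meshes = {
      stopifnot(!is.null(cfg$mesh_files))
      purrr::imap(cfg$mesh_files, function(paths, organ) {
        ms <- lapply(paths, read_mesh)
        names(ms) <- tools::file_path_sans_ext(basename(paths))
        lapply(ms, decimate_smooth_center,
               target_vertices = cfg$target_vertices)
      })
    },
    features = NULL))

  if (!is.null(meshes) && !is.null(cfg$flip_axis))
    meshes <- purrr::map(meshes, function(org)
      purrr::map(org, flip_mesh_axis, axis = cfg$flip_axis))

  blocks <- if (cfg$mode == "features") {
    with_stage("features", {
      stopifnot(!is.null(cfg$feature_files))
      purrr::imap(as.list(cfg$feature_files), function(path, organ)
        standardize_features(read_feature_matrix(path, organ = organ)))
    })
  } else {
    corresponded <- with_stage("registration", {
      if (cfg$correspondence == "register")
        purrr::map(meshes, function(org) register_organ_set(org))
      else {
        counts <- unlist(purrr::map(meshes, function(org)
          purrr::map_int(org, n_vertices)))
        if (length(unique(counts)) != 1L)
          stop("byindex correspondence requires one shared vertex count")
        meshes
      }
    })
    with_stage("features", {
      v <- if (inherits(corresponded[[1]], "registered_organ_set"))
        n_vertices(corresponded[[1]]$meshes[[1]])
      else n_vertices(corresponded[[1]][[1]])
      pairs <- sample_landmark_pairs(v, cfg$n_pairs, cfg$pairs_seed)
      purrr::imap(corresponded, function(org, nm)
        standardize_features(build_feature_matrix(org, pairs, organ = nm)))
    })
  }
  organs <- names(blocks)
  ids <- colnames(blocks[[1]])

  embeddings <- list()
  mcia <- NULL
  center_distances <- NULL
  if ("mcia" %in% cfg$methods) {
    with_stage("mcia", {
      mcia <- mcia_fit(blocks, n_axes = cfg$n_axes,
                       block_scaling = cfg$block_scaling)
      embeddings$mcia <- purrr::imap(mcia$block_scores, function(m, org)
        embedding_2d(m[, 1:2, drop = FALSE], method = "mcia-block",
                     organ = org, ids = ids))
      center_distances <- summed_center_distances(mcia)
    })
  }
  if ("pca" %in% cfg$methods)
    embeddings$pca <- with_stage("pca",
      purrr::map(blocks, pca_embed, n_axes = cfg$n_axes))
  if ("tsne" %in% cfg$methods)
    embeddings$tsne <- with_stage("tsne",
      purrr::map(blocks, tsne_embed, perplexity = cfg$tsne_perplexity,
                 seed = cfg$tsne_seed, iters = cfg$tsne_iters))

  regions <- with_stage("bagplot",
    purrr::imap_dfr(embeddings, function(per_organ, method)
      purrr::imap_dfr(per_organ, function(emb, organ) {
        bp <- compute_bagplot(cbind(emb$dim1, emb$dim2),
                              fence_factor = cfg$fence_factor)
        tibble::tibble(method = method, individual = emb$individual,
                       organ = organ, region = bp$regions,
                       depth = bp$depths)
      })))

  robustness <- with_stage("robustness",
    regions |>
      dplyr::group_by(.data$method) |>
      dplyr::group_modify(~max_same_region_count(.x)) |>
      dplyr::ungroup())
  comparison <- if (length(unique(robustness$method)) >= 2)
    with_stage("robustness",
      compare_methods(split(robustness$count, robustness$method)))
  else NULL

  run <- structure(list(features = blocks, embeddings = embeddings,
                        mcia = mcia, center_distances = center_distances,
                        regions = regions, robustness = robustness,
                        comparison = comparison, truth = truth,
                        config = cfg),
                   class = "morphomcia_run")
  if (!is.null(cfg$out_dir)) write_run_outputs(run, cfg$out_dir)
  run
}

#' @export
print.morphomcia_run <- function(x, ...) {
  cat(sprintf("<morphomcia_run> %d organs x %d individuals; methods: %s\n",
              length(x$features), ncol(x$features[[1]]),
              paste(names(x$embeddings), collapse = ", ")))
  if (!is.null(x$comparison))
    cat(sprintf("Kruskal-Wallis p = %.4g across methods\n",
                x$comparison$kruskal$p))
  invisible(x)
}

write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  num <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)
  for (method in names(run$embeddings))
    for (organ in names(run$embeddings[[method]])) {
      emb <- run$embeddings[[method]][[organ]]
      readr::write_csv(tibble::as_tibble(emb),
                       file.path(out_dir, sprintf("%s_%s.csv", organ, method)))
    }
  readr::write_csv(run$regions, file.path(out_dir, "regions.csv"))
  readr::write_csv(run$robustness, file.path(out_dir, "robustness.csv"))
  if (!is.null(run$center_distances))
    readr::write_csv(run$center_distances,
                     file.path(out_dir, "center_distances.csv"))
  if (!is.null(run$mcia)) {
    pe <- tibble::as_tibble(run$mcia$pseudo_eigenvalues, rownames = "organ")
    readr::write_csv(pe, file.path(out_dir, "pseudo_eigenvalues.csv"))
    readr::write_csv(tibble::tibble(
      axis = seq_len(run$mcia$n_axes),
      objective = run$mcia$objective,
      variance_explained = run$mcia$variance_explained),
      file.path(out_dir, "scree.csv"))
    ctr <- tibble::as_tibble(run$mcia$centers)
    ctr$individual <- run$mcia$ids
    readr::write_csv(ctr[, c("individual", setdiff(names(ctr), "individual"))],
                     file.path(out_dir, "centers.csv"))
  }
  report <- list(
    n_individuals = ncol(run$features[[1]]),
    organs = names(run$features),
    methods = names(run$embeddings),
    kruskal_p = if (!is.null(run$comparison)) run$comparison$kruskal$p else NULL,
    pairwise = if (!is.null(run$comparison))
      as.list(stats::setNames(run$comparison$pairwise$p_holm,
                              paste(run$comparison$pairwise$method1,
                                    run$comparison$pairwise$method2,
                                    sep = "_vs_"))) else NULL)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
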