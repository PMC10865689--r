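Package: morphomcia
Title: Multi-Organ 3-D Shape Analysis with Multiple Co-Inertia and Bagplots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the joint distribution of 3-D organ shapes
    across a cohort. Converts organ-labelled voxel volumes into clean triangle
    meshes, aligns them to a template with two-step coherent point drift and
    establishes vertex correspondence with the Hungarian algorithm, extracts
    per-organ shape feature matrices (pointwise mean curvature,
    Euclidean-to-geodesic distance ratios at seeded landmark pairs, and the
    surface-area-to-volume ratio), and projects the per-organ feature blocks
    into one shared low-dimensional space with multiple co-inertia analysis
    (alongside per-organ PCA and t-SNE). Tukey halfspace-depth bagplots
    classify every organ of every individual as bag, fence or outlier, and a
    per-individual location-robustness statistic compares how consistently the
    projection methods place an individual. A seeded synthetic-cohort
    generator with correlated deformation factors and planted outliers makes
    the full pipeline testable without any imaging download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    Rcpp,
    stats,
    utils,
    Matrix,
    igraph,
    clue,
    Rtsne,
    RNifti,
    EBImage,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    readr,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ade4,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
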