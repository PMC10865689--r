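---
title: "Multi-organ 3-D shape analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-organ 3-D shape analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A cohort study with several 3-D organ segmentations per individual yields
one high-dimensional shape feature matrix *per organ*. Classical ordination
(PCA, t-SNE) embeds each organ separately, so the same individual can look
central in one organ's embedding and extreme in another's, and there is no
principled way to ask "is this *individual* an outlier?" rather than "is
this *organ* an outlier?". `morphomcia` addresses this by projecting all
per-organ feature blocks into one shared plane with multiple co-inertia
analysis (MCIA), classifying every organ of every individual into bagplot
regions (bag / fence / outlier), and summarizing per individual how many of
its organs agree on a region — a location-robustness statistic that can be
compared across projection methods.

# From label volumes to comparable meshes

Input segmentations are NIfTI-1 label volumes (`read_label_volume()`).
Each organ mask is cleaned slice by slice (`clean_mask_slices()`):
morphological opening and closing with a 5×5 box kernel, then filling of
enclosed background, applied independently to every axial slice. Opening
removes speckle below the kernel scale — note that this also removes any
structure smaller than about 5×5 pixels, so a mask must resolve its organ by
a comfortable margin.

`extract_mesh()` extracts the iso-0.5 surface of the binary field. It uses
marching **tetrahedra** (each grid cell split into the six Kuhn tetrahedra
around its main diagonal): on a binary field this produces the same family
of isosurfaces as marching cubes, but it is free of the ambiguous cube
configurations and needs no case tables, which makes the implementation
short enough to verify directly. The decomposition is translation-invariant
across cells, so shared cell faces triangulate identically and the surface
is watertight by construction; the volume enclosed for a solid voxel block
agrees with the voxel count to well under 15 %. Only the largest connected
surface component is kept (paired organs can opt out via
`largest_only = FALSE` and then `split_bilateral()`, which assigns
left/right by centroid along the first axis — radiological convention,
configurable — and refuses inputs that do not have exactly two components;
fused organs are a data problem we decline to cut). Orientation flipping is
an explicit per-dataset flag (`flip_mesh_axis()`), never a heuristic.

Meshes are then conditioned for registration (`decimate_smooth_center()`):
quadric edge-collapse decimation to a common vertex budget (default 1000,
enforced within ±2 %; the collapse respects the link condition and a
normal-flip test, so genus-0 meshes keep Euler characteristic 2), Taubin
smoothing (λ = 0.5, μ = −0.53, 10 passes — the classic low-shrink pairing;
a sphere's radius changes by < 1 %), and mean-centering.

# Registration and correspondence

Each organ is aligned to a template — the mesh whose enclosed volume is
closest to the cohort median (ties to the lowest index). Alignment is
two-step coherent point drift: `cpd_affine()` then `cpd_nonrigid()`. Both
treat the moved source points as isotropic Gaussian mixture centroids for
the target and run EM from the identity, so registration is deterministic.
Point sets are internally centred and scaled to unit RMS radius; the
non-rigid kernel width `beta = 2` and regularization `lambda = 2` (the
original CPD defaults) are therefore expressed in those normalized units.
The EM objective (negative log-likelihood) is non-increasing and iteration
stops when its relative change drops below `tol = 1e-5` (or at
`max_iters = 100`, with a warning and the best iterate).

Vertex correspondence is the exact square linear assignment between the
non-rigidly moved source vertices and the template vertices under Euclidean
cost (`hungarian_correspondence()`, via `clue::solve_LSAP`; optimality is
cross-checked against exhaustive permutation in the tests). Features are
computed on the *moved* geometry in template vertex order, because
curvature must be comparable vertex-wise across individuals. Decimation
forces all meshes to exactly the template's vertex count, making the
correspondence a bijection.

# Shape features

Per organ and individual, `build_feature_matrix()` stacks

* per-vertex mean curvature (V features): the cotangent-Laplacian
  mean-curvature normal with barycentric vertex areas, `H = ||Δv||/2`,
  signed by agreement with the inward normal so convex regions are positive
  (sphere of radius r: `H = 1/r`, within 5 % at ~1000 vertices; degenerate
  triangles fall back to the 1-ring average with a warning);
* Euclidean-to-geodesic distance ratios at `n_pairs = 500` seeded landmark
  pairs (drawn once per organ family with `sample_landmark_pairs()` and
  reused for every individual). Geodesics are Dijkstra shortest paths on
  the edge graph — an upper bound on the exact polyhedral geodesic, about
  6 % high for antipodal points at this resolution — so ratios lie in
  (0, 1];
* the surface-area-to-volume ratio (1 feature).

That gives `d = V + n_pairs + 1` features (1501 at the defaults).
`standardize_features()` centers each feature and scales to unit
*population* variance (divisor n, not n−1), so the total inertia of a
standardized block under uniform weights `w_i = 1/n` equals its feature
count exactly; zero-variance features (e.g. a ratio that equals 1 for every
individual because the pair sits on a straight edge chain) are dropped with
a warning.

# Dimension reduction

With blocks \(X_s\) (features × individuals, standardized), uniform sample
weights \(W = \mathrm{diag}(1/n)\) and identity feature metrics, the
inertia of a block is \(\mathrm{trace}(X^\top Q X W)\) — a sum of variances
— and the co-inertia of two blocks is
\(\mathrm{trace}(X Q X^\top W Y R Y^\top W)\), the sum of squared
W-covariances over all feature pairs (`inertia()`, `coinertia()`, both
tested against their double-sum forms).

`mcia_fit()` maximizes, axis by axis, the sum over blocks of squared
covariances between the block projection \(X_s^\top u_s\) (with
\(\lVert u_s\rVert = 1\)) and a common synthetic axis \(h\) (with
\(h^\top W h = 1\)). The optimum is the top eigenpair of
\(K = \sum_s W^{1/2} X_s^\top X_s W^{1/2}\): \(h\) is the rescaled leading
eigenvector and \(u_s \propto X_s W h\). Later axes deflate each block by
projecting out \(h\) under the W-inner product; this is algebraically the
eigendecomposition of K, so the per-axis objectives are its decreasing
eigenvalues, the synthetic axes are mutually W-orthogonal, and the per-axis
variance explained is the eigenvalue over \(\mathrm{trace}(K)\). A block's
contribution \(\mathrm{Cov}^2(X_s^\top u_s, h)\) per axis is reported as its
pseudo-eigenvalue; their per-axis sum equals the objective.

Two conventions are worth making explicit:

* **Block pre-scaling.** After standardization each block is divided by the
  square root of its total inertia (`block_scaling = "unit_inertia"`), so an
  organ cannot dominate the objective merely by having more features; set
  `"none"` to disable.
* **Score normalization.** Block sample scores and the per-individual
  synthetic centers (the mean of the block scores) are rescaled to unit
  W-variance per axis. This makes "identical blocks ⇒ centers coincide with
  the block scores" exact and matches how MCIA plots are usually drawn; the
  raw covariance structure is retained in the pseudo-eigenvalues. The
  shorter the lines from the organ scores to the center, the more the
  organs agree (`summed_center_distances()` quantifies this per
  individual).

Axis signs are fixed by making the largest-magnitude loading positive, so
plots are reproducible. For comparison, `pca_embed()` embeds one block by
principal components of its column cloud (same sign rule), and
`tsne_embed()` runs exact t-SNE (perplexity `min(30, floor((n-1)/3))`,
1000 iterations, early exaggeration 12 for 250, seeded initialization —
deterministic for a fixed seed).

# Bagplots and the location-robustness statistic

`compute_bagplot()` builds the two-dimensional boxplot analogue from exact
Tukey halfspace depth (angular sweep; verified against an \(O(n^3)\) brute
force). The depth regions \(D_k=\{x:\mathrm{depth}(x)\ge k\}\) are computed
exactly as intersections of the halfplanes bounded by lines through data
point pairs with at most \(k-1\) points strictly beyond them; the depth
median is the area centroid of the deepest region.

The bag should hold the deepest 50 % of the points. A subtlety forces a
tie rule: every sample point of depth k lies exactly *on* the contour of
\(D_k\) (a supporting line through it and another data point exists), so no
single interpolation factor between the two bracketing contours can
separate points of the boundary depth level. The bag therefore admits
boundary-level points in order of distance to the depth median (ties by
index) until exactly \(\lfloor n/2\rfloor\) points are inside, and takes
the convex hull of the admitted points; boundary points count as inside.
For points in general position the bag then holds exactly half the data.
The fence inflates the bag threefold about the depth median
(`fence_factor = 3`, the classic construction); points beyond it are
outliers. Collinear data are refused with a suggestion to jitter.

Per projection method, each organ's 2-D coordinates get their own bagplot
(for MCIA: the organ's block scores within the common space), every
individual-organ pair receives a region label, and
`max_same_region_count()` reduces this to the per-individual maximum number
of organs sharing one region — by pigeonhole at least \(\lceil S/3\rceil\).
`compare_methods()` tests the resulting count distributions across methods
with the tie-corrected Kruskal–Wallis test and all pairwise two-sided
Mann–Whitney U tests. Because the counts are small integers, ties are the
rule, and `stats::wilcox.test` cannot give exact p-values under ties, the
exact two-sided p (group sizes ≤ 20) is computed by a shift-algorithm
dynamic program over the permutation distribution of the midrank sum; it
matches full enumeration on small cases. Raw and Holm-adjusted p-values are
both reported, two-sided throughout.

# The synthetic cohort

`generate_cohort()` emulates the study design without any imaging data:
`n = 30` individuals × 3 organ families (liver/kidney/spleen-scale base
ellipsoids, semi-axes 80/60/50, 35/25/55 and 45/30/35 mm), each mesh a
star-shaped surface \(r(u) = r_{\mathrm{ellipsoid}}(u)\,(1 + \sum_k a_k
B_k(u))\) over one fixed ~1000-vertex sphere triangulation, so all meshes
are in exact vertex correspondence by construction. The basis functions
\(B_k\) are degree-2 and degree-3 spherical-harmonic-like polynomials,
normalized to unit maximum; degree-1 terms are deliberately excluded
because to first order they translate the shape, which centering and the
translation-invariant features would erase.

The coefficients mix shared structure and noise:
\(a = \gamma_s\,P\,(\alpha \odot z_i) + \varepsilon\), with per-individual
latent factors \(z_i \sim N(0, I_2)\) shared across organs (scaled by the
organ loading \(\gamma_s\)), a fixed pattern matrix \(P\) feeding each
factor into a disjoint basis group, factor amplitudes
\(\alpha = (0.04, 0.012)\) relative radius — a clearly dominant first
variation mode, as organ shape-model studies typically report — and
independent coefficient noise \(\varepsilon \sim N(0, 0.004^2)\),
subordinate to the shared factors. Planted outliers multiply an
individual's coefficients by \(\kappa\) (default scenarios use
\(\kappa = 5\)) for one organ or for all (`organ = "ALL"`); a deformation
driving the radius non-positive is refused rather than silently
self-intersecting. Everything is reproducible from the spec's single seed.

Under these conditions the first MCIA axis recovers the first latent
factor (|r| ≥ 0.9 in the tests, typically ≥ 0.99) and a κ = 5
whole-individual outlier lands beyond the fence in at least half of its
organs' MCIA bagplots across seeds.

# Pipeline, problem sizes and determinism

`run_pipeline()` chains the stages from one `pipeline_config()` and tags
any error with its stage name. In `simulate` mode the generated meshes
share a triangulation, so the pipeline defaults to
`correspondence = "byindex"` and skips CPD + assignment, which carry no
statistical content there; registration is exercised and validated on its
own (transform-recovery tests and `correspondence = "register"` for mesh
inputs). All randomness flows from named seeds, and re-running a config
reproduces every output file byte for byte.

The test suite runs the geometry calibrations at ~2500 vertices, the
single-run pipeline checks at the 1000-vertex default, and the multi-seed
recovery studies (one clean cohort plus twenty outlier cohorts) on
642-vertex spheres with 500 landmark pairs — the package's chosen desk
scale, at which a full cohort run takes a few seconds without changing any
statistical conclusion.

# Known limitations

* The synthetic cohort exercises the statistics end to end, but its shapes
  are star-shaped, smooth, and in exact correspondence; it does not probe
  segmentation artefacts, partial organs, registration failure on highly
  concave anatomy, or scanner-dependent effects. Passing tests show the
  machinery is correct, not that real CT cohorts will separate as cleanly.
* Graph geodesics overestimate true surface geodesics on coarse meshes;
  ratios are comparable across individuals (same triangulation budget) but
  are not exact polyhedral distances.
* The bagplot's exact depth regions cost roughly \(O(n^3)\); cohorts up to
  a few hundred individuals are comfortable, tens of thousands are not.
* MCIA here standardizes once and applies no further internal transform;
  other MCIA implementations add their own block weighting, so axes agree
  up to such conventions (the dominant axis matches `ade4::mcoa` to
  |r| > 0.99 on structured data in the tests).
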