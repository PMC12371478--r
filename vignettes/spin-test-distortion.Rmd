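---
title: "Benchmarking spin tests: models, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking spin tests: models, diagnostics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Comparing two per-vertex brain maps usually starts with a Pearson
correlation and ends with a p-value. Because cortical maps are spatially
autocorrelated, neighbouring vertices are not independent observations, and
naive parametric or label-permutation p-values are anticonservative. The
spin test addresses this by building the null from rotations: a map is
projected to the spherical registration surface, the sphere is randomly
rotated, values are carried back by nearest-neighbour matching, and the
observed correlation is compared with correlations against these "spun"
surrogates.

The catch is geometric. A rotation of a sphere is an isometry, but the
projection between a folded cortical surface and its sphere is not — no
isometric mapping exists between surfaces of different Gaussian curvature.
Distances among vertices are distorted on the way to the sphere and again
on the way back, so spun surrogates do not carry exactly the
autocorrelation of the original map. spinbench implements the machinery to
generate controlled test beds, quantify that distortion with Moran
statistics, measure its consequence (false-positive inflation), and
evaluate a mitigation (removing the worst-distorting rotations).

```{r, eval = FALSE}
library(spinbench)
pair  <- make_bumpy_pair(3, amplitude = 0.25, harmonic_order = 4,
                         radius = 100, seed = 1)
maps  <- generate_ensemble(pair$surface, lengths = c(5, 25, 50),
                           n_maps = 100, seed = 101)
spins <- generate_spin_ensemble(pair, 3000, seed = 202)
spins <- score_ensemble_quality(spins, pairwise_euclidean(pair$surface))
removal_sweep(maps, spins, thresholds = c(0, 90), n_sample = 300, seed = 77)
```

## Synthetic geometry

Real cortical meshes are large, licensed artifacts; the package instead
manufactures the geometric situation that matters. `make_icosphere()`
builds a subdivided icosahedron (the closest practical approximation to a
uniform spherical mesh; `10 * 4^s + 2` vertices). `make_bumpy_pair()`
produces a matched pair: the icosphere in the spherical role, and a
"cortical-like" surface obtained by moving each vertex radially to
`radius * (1 + amplitude * f)`, where `f` is a seeded zero-mean random
combination of real spherical harmonics up to `harmonic_order`, rescaled
to `max |f| = 1`. Radial displacement means the spherical projection of
the bumpy surface is exactly the icosphere — the vertexwise correspondence
every spin test assumes. The default amplitude 0.25 with order-4 harmonics
yields gyrus-scale undulations that reduce the surface-to-sphere
pairwise-distance correlation to about 0.99: a *mild* distortion compared
with a real pial surface, which is why the package's benchmark contrasts
are direction-level rather than magnitude-level reproductions.

What the fixture does not emulate: uneven vertex spacing from surface
inflation (sulci denser than gyri), the medial wall, bilateral meshes, or
registration-driven distortion patterns. Passing benchmarks here show the
machinery is correct and the distortion mechanism operates; absolute
inflation levels on real templates must be measured on real templates
(the readers `read_freesurfer_geometry()` / `read_surface_gifti()` take
fsaverage-family files directly).

## Random fields

Test maps are stationary Gaussian fields with the Gaussian variogram

$$\gamma(h) = \sigma^2\!\left[1 - e^{-(sh/l)^2}\right],$$

with length `l` (mm), sill `sigma2`, and rescale `s` defaulting to
`sqrt(pi)/2`, the convention geostatistics toolboxes use for the Gaussian
model so that `l` is comparable across variogram families; `s = 1` recovers
the bare exponent. Fields are realized by the randomization method:

$$u(x) = \sqrt{\sigma^2/N}\,\sum_{i=1}^{N}
  \left[Z_{1,i}\cos(k_i \cdot x) + Z_{2,i}\sin(k_i \cdot x)\right],$$

with `N = 1000` modes by default. Two derivations pin the free choices.
The prefactor must be `sqrt(sigma2/N)` for `Var[u] = sigma2`. The
wavevectors follow the spectral measure of the Gaussian covariance: for
`k ~ N(0, v I_3)`, `E[cos(k.h)] = exp(-v|h|^2/2)`, and matching
`sigma^2 exp(-(sh/l)^2)` forces per-component standard deviation
`sqrt(2) s / l`. Both facts are enforced by tests: a 10,000-field
Monte-Carlo empirical variogram agrees with the closed form within 5% of
the sill, and the sampled spectral measure reproduces the Gaussian
correlation independently of the field-generation path.

`generate_ensemble()` reuses the amplitudes `Z` and the underlying
wavevector variates across lengths (`shared_draws = TRUE`), so map *m* at
two lengths differs only through the variogram scale. Because the
cross-length covariance is `exp(-(c_1-c_2)^2|x|^2/2)` in the rescaled
wavenumbers, this coupling is strong only for nearby lengths — maps at
5 mm and 50 mm on a radius-100 sphere are effectively independent even
with shared draws, which is the intended behaviour (consistent
comparisons, not duplicated maps).

## Moran statistics

Spatial autocorrelation is quantified by Moran's I with inverse-distance
weights, `w_ij = 1/d_ij` (zero diagonal), row-normalized by default so the
total weight `W0` equals the vertex count. Values are standardized with the
*population* (divide-by-n) standard deviation; under that convention
`sum(z^2) = n` and the cross-product form `(1/W0) sum_ij w_ij z_i z_j` is
the textbook statistic with permutation-null mean `-1/(n-1)` (verified by
full enumeration at n = 4, 5, 6).

The local decomposition `I_i = z_i sum_j w_ij z_j` satisfies
`(1/W0) sum_i I_i = I` identically, and the per-vertex change under a spin
factors as `delta I_i = z_i sum_j z_j (w_ij - w'_ij)`, where `w'` is the
original weight matrix re-indexed through the inverse permutation. The
stored convention is *pull* indexing — a spin is a map `perm` with
`u_spun[i] = u[perm[i]]` — and the re-indexing convention is the unique one
under which `(1/W0) sum_i delta I_i` equals the difference of the two
global Moran's I values; that identity is asserted to 1e-10 over random
permutations, so the convention cannot silently drift.
`moran_scatter()` exposes the same decompositions as (value, lag) pairs
whose products are the local statistics.

Weight matrices are dense. A guard rejects meshes beyond 20,000 vertices
(a 10,242-vertex hemisphere template fits comfortably in memory; full
inverse-distance weighting is deliberate — the statistic is about *all*
pairwise relationships, not a k-nearest sparsification).

## The spin procedure

Rotations are sampled from the Haar measure on SO(3): QR-factorize a 3x3
standard-normal matrix, multiply each column of Q by the sign of the
corresponding diagonal entry of R, and negate the last column if the
determinant is -1. The construction is validated statistically (octant
occupancy of a rotated fixed vector over 50,000 draws) rather than by
matching any particular reference implementation, since sign conventions
differ across QR routines.

`build_spin()` recentres the sphere to its centroid (file meshes may be
offset), rotates, and matches each *original* vertex to its nearest
rotated vertex, ties broken by lowest index for cross-platform
determinism. Pull semantics guarantee every output vertex receives a value;
the price is that sources may repeat, so a "spin" is formally an index map
rather than a bijection. `delta_local_morans_i()` therefore insists on a
true bijection (its identity is only exact there), while every other
consumer accepts general index maps.

Spin quality is the Pearson correlation between the upper triangles of the
cortical-surface distance matrix and its re-indexing through the spin. An
identity spin scores exactly 1; on a sphere, rotations lose only
nearest-neighbour discretization (≥ 0.99 on a 642-vertex icosphere); on a
distorted pair the score drops, and it anti-correlates with how much the
spin perturbs Moran's I. For meshes above 5,000 vertices the correlation is
computed on a seeded uniform vertex subsample and flagged in provenance.
`threshold_ensemble()` removes the lowest-quality percentile of spins
(quantile cut, ties surviving) and samples a fixed number of survivors so
null ensembles stay size-matched across thresholds.

## Inference and benchmarks

`spin_pvalue()` uses the inclusive two-sided convention
`p = (1 + #{|r_null| >= |r_obs|}) / (n_spins + 1)`, which is the
field-standard choice and guarantees `p > 0`; sidedness and the add-one
are switches so other conventions can be emulated. The first argument is
the map that gets spun.

`fpr_experiment()` is the calibration benchmark: all maps are independent
draws, so every rejection is a false positive and a calibrated test yields
mean FPR `alpha`. `moran_deviation()` measures `I(u) - mean_s I(u_spun)`;
`fpr_vs_deviation()` correlates the two per-map quantities; and
`removal_sweep()` repeats the FPR experiment under progressive
quality-based removal, also tracking the mean absolute correlation between
each map and its surviving nulls — the warning signal that overly
aggressive removal leaves nulls that resemble the original map too
closely, trading false positives for false negatives.

### Problem sizes

The package's benchmark configuration ("desk" preset, also the scale used
by the test suite and the acceptance script) is: subdivision-3 icosphere
(642 vertices, radius 100 mm), 100 maps per length at lengths
{5, 25, 50} mm, 300 spins, 3,000-spin scored ensembles for the removal
sweep. These sizes give ~10,000 tested pairs per length (binomial s.e.
~0.002 on an FPR of 0.05) and complete in minutes on one CPU. The "paper"
preset (1,000 maps, 1,000 spins from a 10,000 ensemble, six lengths from
1 to 50) supports full-scale runs on real fsaverage5 meshes, and is
configuration, not a different code path.

## Numerical choices

* **Geodesics** are Dijkstra shortest paths over the triangulation edge
  graph with Euclidean edge weights. This overshoots exact polyhedral
  geodesics by up to ~5–10% on coarse spheres (path confined to edges),
  deterministically and without extra dependencies; for row-normalized
  inverse-distance weights the effect on Moran statistics is a mild,
  monotone reweighting. The triangle inequality and the
  geodesic-dominates-chord property are tested.
* **Ties** in nearest-neighbour matching break to the lowest vertex index.
* **Degenerate inputs**: constant maps are rejected wherever a Moran
  statistic or correlation is undefined; duplicate vertices are rejected
  at weight construction (zero distances); disconnected meshes are
  rejected with component sizes; quality needs ≥ 3 vertices.
* **Seeds**: every public generator takes an explicit seed, saves and
  restores the caller's RNG state, and derives independent substream seeds
  for units of work from one master seed, so ensembles are reproducible
  end to end and invariant to evaluation order.
* **Monte-Carlo tests** use 3-standard-error tolerances at fixed seeds.

## Known limitations

* Nearest-neighbour resampling on a *discrete* sphere is not exactly an
  isometry: the half-edge-scale jitter slightly decorrelates spun maps, so
  surrogate Moran's I is biased a little low even on a perfect sphere. The
  absolute bias is tiny (~0.002 at 642 vertices) and shrinks with mesh
  resolution, but the *standardized* Moran's I divides by the (equally
  shrinking) surrogate spread, so zI on a sphere sits near +1 at coarse
  resolution rather than at 0. Interpret zI comparatively across maps on a
  fixed mesh, not as an absolute calibration score. The p-value machinery
  is unaffected — sphere FPR calibration holds at 0.05.
* The bumpy-pair fixture produces mild, direction-level inflation;
  magnitude-level reproduction of published numbers requires the real
  template geometry at full scale.
* Only single-hemisphere meshes; no medial-wall masking by default (an
  optional vertex subset can be applied upstream of the weight matrix);
  no parcel-level spins; no alternative null families (variogram-matching,
  eigenstrapping) — those are different estimators, not variants of this
  one.
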