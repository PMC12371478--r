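# spinbench

Spin tests for surface maps, with the diagnostics to know when to trust
them.

## The problem

The spin test is the standard spatial permutation procedure for judging
whether two per-vertex brain maps are more similar than spatial
autocorrelation alone would produce: project a map to the spherical
registration surface, apply a random rotation, carry the values back by
nearest-neighbour matching, and compare the observed map-to-map Pearson
correlation with correlations against these spun surrogates. Rotating a
sphere preserves distances exactly — but the projection between a folded
cortical surface and its sphere cannot (the two surfaces have different
Gaussian curvature), so spun surrogates imperfectly preserve the spatial
autocorrelation of the original map, and the test's false positive rate
creeps above its nominal level.

spinbench is for methodologists and pipeline builders who want to (a) run
spin tests, (b) measure how much projection distortion is biasing them on
a given geometry, and (c) mitigate that bias by quality-screening the
rotations.

## What it computes

* **Spatially autocorrelated test maps** via the randomization method
  under a Gaussian variogram
  γ(h) = σ²[1 − e^{−(sh/l)²}],
  u(x) = √(σ²/N) Σᵢ [Z₁ᵢ cos(kᵢ·x) + Z₂ᵢ sin(kᵢ·x)],
  with kᵢ drawn from the model's spectral density.
* **Moran's I** with row-normalized inverse-distance weights,
  I = (1/W₀) Σᵢⱼ wᵢⱼ zᵢ zⱼ, its local decomposition Iᵢ = zᵢ Σⱼ wᵢⱼ zⱼ,
  and the per-vertex change under a spin,
  ΔIᵢ = zᵢ Σⱼ zⱼ (wᵢⱼ − w′ᵢⱼ), whose normalized sum equals the global
  Moran difference.
* **Spin ensembles**: Haar-uniform rotations (QR construction),
  nearest-neighbour vertex maps, a per-spin quality score (correlation of
  the surface distance matrix with its re-indexing under the spin), and
  quality-thresholded subsampling.
* **Benchmarks**: spin-test p-values, the all-pairs false-positive-rate
  experiment, Moran-deviation diagnostics, and the removal-threshold
  sweep.
* **I/O**: FreeSurfer binary geometry, GIFTI `.surf.gii` / `.func.gii`
  (ASCII, base64, gzipped base64), single-column CSV maps; ensembles
  persist to CSV + JSON manifests.

## Worked example

A synthetic "cortex": an icosphere (642 vertices, radius 100 mm) deformed
by smooth random bumps, paired with its exact spherical projection. Maps
are generated on the bumpy surface; spins are built on the sphere — the
situation every spin test faces.

```r
library(spinbench)

pair  <- make_bumpy_pair(3, amplitude = 0.25, harmonic_order = 4,
                         radius = 100, seed = 1)
maps  <- generate_ensemble(pair$surface, lengths = c(5, 25, 50),
                           n_maps = 100, seed = 101)
spins <- generate_spin_ensemble(pair, 3000, seed = 202)
spins <- score_ensemble_quality(spins, pairwise_euclidean(pair$surface))
round(range(spins$qualities), 3)
#> [1] 0.959 0.995

removal_sweep(maps, spins, thresholds = c(0, 90), n_sample = 300,
              alpha = 0.05, seed = 77)
#> <sweep_result> thresholds: 0, 90%; lengths: 5, 25, 50
#>  threshold length   mean_fpr null_similarity
#>          0      5 0.05222222      0.03177917
#>          0     25 0.05353535      0.08454402
#>          0     50 0.05585859      0.17445222
#>         90      5 0.05404040      0.03314618
#>         90     25 0.05090909      0.10908846
#>         90     50 0.03474747      0.24000054
```

Reading the table: with no quality screening (threshold 0) the false
positive rate at the nominal 0.05 level climbs with the autocorrelation
length — 0.056 at 50 mm — because smoother maps are hurt more by
projection distortion. Removing the worst 90% of spins by quality pulls
the 50 mm rate down to 0.035, at the cost of surrogates that resemble the
original map more closely (null similarity 0.17 → 0.24, the false-negative
warning sign). On the undistorted sphere the same pipeline stays at 0.05
across lengths.

Testing one pair of maps against the screened ensemble:

```r
x <- maps$maps[["50"]][, 1]; y <- maps$maps[["50"]][, 2]
spin_pvalue(x, y, threshold_ensemble(spins, 90, 300, seed = 7))
#> Spin test: r = 0.0282, p = 0.8837 (two.sided, 300 spins)

W <- inverse_distance_weights(pairwise_euclidean(pair$surface))
round(morans_i(x, W), 4)                      # the map's autocorrelation
#> [1] 0.1764
round(moran_deviation(x, spins, W)$deviation, 4)  # what spinning loses
#> [1] 0.0016
```

The two maps are independent draws; the spin test correctly declines to
call r = 0.03 significant. The Moran deviation (empirical minus mean spun
I) is the per-map distortion diagnostic that correlates with per-map false
positive rates.

## Command line

```sh
Rscript inst/cli/spinbench.R fpr-bench --preset desk --seed 1 --out bench/
Rscript inst/cli/spinbench.R spin-test --x x.csv --y y.csv --spins bench/spins --out out/
```

Subcommands: `simulate-maps`, `gen-spins`, `spin-qc`, `spin-test`,
`fpr-bench`, `moran`. Configuration lives in a YAML file (`--config`);
flags override file values; every run writes a `manifest.json` from which
its outputs can be regenerated.

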