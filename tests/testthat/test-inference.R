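test_that("p-value counting follows the inclusive convention", {
  r_null <- matrix(c(0.1, 0.2, 0.3, 0.4), ncol = 1L)
  expect_equal(spinbench:::null_pvalues(r_null, 0.25, "two.sided", TRUE),
               (1 + 2) / 5)
  expect_equal(spinbench:::null_pvalues(r_null, 0.25, "two.sided", FALSE),
               2 / 4)
  expect_equal(spinbench:::null_pvalues(r_null, -0.25, "two.sided", TRUE),
               (1 + 2) / 5)
  expect_equal(spinbench:::null_pvalues(r_null, 0.25, "greater", TRUE),
               (1 + 2) / 5)
  expect_equal(spinbench:::null_pvalues(r_null, 0.25, "less", TRUE),
               (1 + 2) / 5)
})

test_that("spin_pvalue hits its extreme-statistic bounds", {
  s <- small_sphere()
  spins <- generate_spin_ensemble(s, 30, seed = 17)
  set.seed(2)
  x <- stats::rnorm(n_vertices(s))
  # identical maps: no spun version reproduces |r| = 1 on a generic map
  res <- spin_pvalue(x, x, spins)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 31)
  # testing a map against a spun version of itself: the generating spin ties
  x_spun <- x[spins$permutations[7L, ]]
  res2 <- spin_pvalue(x, x_spun, spins)
  expect_gte(res2$p, 2 / 31)
  expect_error(spin_pvalue(rep(1, n_vertices(s)), x, spins), "constant")
})

test_that("fpr_experiment counts rejections per map", {
  s <- small_sphere()
  spins <- generate_spin_ensemble(s, 40, seed = 23)
  ens <- generate_ensemble(s, 25, 12, seed = 31, n_modes = 128L)
  maps <- ens$maps[[1L]]
  f <- fpr_experiment(maps, spins, alpha = 0.05)
  expect_length(f$per_map_fpr, 12L)
  expect_true(all(f$per_map_fpr >= 0 & f$per_map_fpr <= 1))
  # count-based rates: fpr * (n_maps - 1) is integral
  expect_equal(f$per_map_fpr * 11, round(f$per_map_fpr * 11),
               tolerance = 1e-9)
  expect_true(all(is.na(diag(f$pvalues))))

  # alpha = 0 rejects nothing
  f0 <- fpr_experiment(maps, spins, alpha = 0)
  expect_true(all(f0$per_map_fpr == 0))

  # permuting map labels permutes the per-map rates identically
  ord <- c(5L, 1L, 12L, 3L, 7L, 2L, 9L, 4L, 11L, 6L, 10L, 8L)
  f_perm <- fpr_experiment(maps[, ord], spins, alpha = 0.05)
  expect_equal(f_perm$per_map_fpr, f$per_map_fpr[ord], tolerance = 1e-12)
})

test_that("p-values are stable in expectation when spins are added", {
  s <- small_sphere()
  full <- generate_spin_ensemble(s, 300, seed = 29)
  half <- spinbench:::subset_ensemble(full, 1:150)
  ens <- generate_ensemble(s, 25, 15, seed = 37, n_modes = 128L)
  maps <- ens$maps[[1L]]
  pairs <- utils::combn(15L, 2L)[, 1:100]
  dp <- vapply(seq_len(ncol(pairs)), function(k) {
    x <- maps[, pairs[1L, k]]; y <- maps[, pairs[2L, k]]
    spin_pvalue(x, y, full)$p - spin_pvalue(x, y, half)$p
  }, numeric(1))
  expect_lt(abs(mean(dp)), 2 / 151)
})

test_that("moran_deviation averages its per-spin values", {
  s <- small_sphere()
  W <- small_sphere_W()
  set.seed(4)
  u <- s$coordinates[, 3L] + stats::rnorm(n_vertices(s), sd = 30)

  ident <- generate_spin_ensemble(s, 2, seed = 1)
  ident$permutations <- matrix(rep(seq_len(n_vertices(s)), 2),
                               nrow = 2, byrow = TRUE)
  d0 <- moran_deviation(u, ident, W)
  expect_equal(d0$deviation, 0, tolerance = 1e-12)

  spins <- generate_spin_ensemble(s, 25, seed = 19)
  d <- moran_deviation(u, spins, W)
  expect_equal(mean(d$per_spin), d$deviation, tolerance = 1e-12)
  expect_equal(d$empirical, morans_i(u, W), tolerance = 1e-12)
})

test_that("fpr_vs_deviation guards degenerate inputs", {
  s <- small_sphere()
  spins <- generate_spin_ensemble(s, 20, seed = 3)
  ens <- generate_ensemble(s, 25, 5, seed = 5, n_modes = 64L)
  # constant per-map FPR (alpha = 0) must be rejected, not correlated
  expect_error(fpr_vs_deviation(ens, spins, small_sphere_W(), alpha = 0),
               "degenerate|at least")
})

test_that("removal sweep at threshold 0 matches a plain subsample", {
  s <- small_sphere()
  ens <- generate_ensemble(s, 25, 10, seed = 41, n_modes = 128L)
  big <- generate_spin_ensemble(s, 60, seed = 43)
  big <- score_ensemble_quality(big, pairwise_euclidean(s))
  sw <- removal_sweep(ens, big, thresholds = 0, n_sample = 30,
                      alpha = 0.05, seed = 11)
  sub <- threshold_ensemble(big, 0, 30,
                            spinbench:::derive_seeds(11, 1L)[1L])
  ref <- fpr_experiment(ens$maps[[1L]], sub, alpha = 0.05)
  expect_equal(sw$per_map$fpr, ref$per_map_fpr, tolerance = 1e-12)
  expect_equal(sw$grid$mean_fpr, mean(ref$per_map_fpr), tolerance = 1e-12)
  expect_identical(sw$cutoffs, -Inf)
})
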