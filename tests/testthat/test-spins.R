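test_that("sampled rotations are proper and reproducible", {
  set.seed(40)
  for (i in 1:20) {
    R <- sample_rotation()
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
  }
  set.seed(41); a <- sample_rotation()
  set.seed(41); b <- sample_rotation()
  expect_identical(a, b)
})

test_that("spins preserve chordal distances before resampling", {
  s <- make_icosphere(2, radius = 100)
  d0 <- pairwise_euclidean(s)$values
  set.seed(5)
  for (i in 1:5) {
    R <- sample_rotation()
    rot <- s$coordinates %*% t(R)
    expect_lt(max(abs(as.matrix(stats::dist(rot)) - d0)), 1e-9)
  }
})

test_that("nearest-neighbour spin construction honours its contract", {
  s <- make_icosphere(2, radius = 100)
  expect_identical(build_spin(s, diag(3)), seq_len(n_vertices(s)))

  # an exact icosahedral symmetry yields a true bijection realizing it
  s0 <- make_icosphere(0, radius = 1)
  R72 <- rotation_about(s0$coordinates[1L, ], 2 * pi / 5)
  perm <- build_spin(s0, R72)
  expect_identical(sort(perm), 1:12)
  resid <- max(sqrt(rowSums(
    ((s0$coordinates %*% t(R72))[perm, ] - s0$coordinates)^2)))
  expect_lt(resid, 1e-9)

  # generic rotations: spun values are drawn from the original multiset
  set.seed(6)
  perm <- build_spin(s, sample_rotation())
  u <- stats::rnorm(n_vertices(s))
  expect_true(all(u[perm] %in% u))

  # recentring: an offset sphere gives the same spins as the centred one
  off <- surface_mesh(s$coordinates + matrix(c(50, -20, 10),
                                             n_vertices(s), 3L, byrow = TRUE),
                      s$triangles, check_connected = FALSE)
  set.seed(9); R <- sample_rotation()
  expect_identical(build_spin(off, R), build_spin(s, R))
})

test_that("spin ensembles are deterministic with provenance", {
  s <- make_icosphere(1, radius = 100)
  a <- generate_spin_ensemble(s, 20, seed = 12)
  b <- generate_spin_ensemble(s, 20, seed = 12)
  expect_identical(a$permutations, b$permutations)
  expect_identical(a$rotations, b$rotations)
  expect_identical(a$seed, 12L)
  expect_identical(a$fingerprint, spinbench:::mesh_fingerprint(s))
  expect_equal(n_spins(a), 20L)
  # continuous rotations: all distinct
  expect_equal(nrow(unique(a$permutations)), 20L)
})

test_that("spin quality scores distance preservation", {
  pair <- make_bumpy_pair(2, amplitude = 0.25, harmonic_order = 4,
                          radius = 100, seed = 1)
  Dsph <- pairwise_euclidean(pair$sphere)
  Dsurf <- pairwise_euclidean(pair$surface)
  n <- n_vertices(pair$sphere)

  expect_equal(score_quality(seq_len(n), Dsurf), 1)
  expect_error(score_quality(1:2, pairwise_euclidean(matrix(stats::rnorm(6), 2L))),
               "3 vertices")

  # on a subdivision-3 icosphere, rotations only lose nearest-neighbour
  # discretization: quality stays above 0.99 against the sphere's own metric
  s3 <- desk_sphere()
  D3 <- pairwise_euclidean(s3)
  set.seed(10)
  q3 <- vapply(1:5, function(i) score_quality(build_spin(s3, sample_rotation()), D3),
               numeric(1))
  expect_true(all(q3 >= 0.99))

  # distortion lowers quality: sphere scores dominate bumpy-surface scores
  spins <- generate_spin_ensemble(pair, 200, seed = 44)
  q_sph <- score_ensemble_quality(spins, Dsph)$qualities
  q_surf <- score_ensemble_quality(spins, Dsurf)$qualities
  expect_lt(mean(q_surf), mean(q_sph))
  wt <- stats::wilcox.test(q_sph, q_surf, alternative = "greater")
  expect_lt(wt$p.value, 0.001)
})

test_that("quality scoring subsamples vertices only on large meshes", {
  s <- make_icosphere(2, radius = 100)
  sp <- generate_spin_ensemble(s, 3, seed = 2)
  D <- pairwise_euclidean(s)
  full <- score_ensemble_quality(sp, D)
  expect_false(full$quality_provenance$subsampled)
  sub <- score_ensemble_quality(sp, D, max_vertices = 100L, seed = 5)
  expect_true(sub$quality_provenance$subsampled)
  expect_equal(sub$quality_provenance$n_scored, 100L)
  # the subsampled score approximates the full one
  expect_lt(max(abs(sub$qualities - full$qualities)), 0.05)
})

test_that("threshold_ensemble removes by quality percentile then samples", {
  s <- make_icosphere(1, radius = 100)
  sp <- generate_spin_ensemble(s, 4, seed = 3)
  sp$qualities <- c(0.1, 0.2, 0.3, 0.4)
  out <- threshold_ensemble(sp, 50, 2, seed = 1)
  expect_true(all(out$qualities >= 0.3))

  expect_error(threshold_ensemble(sp, 50, 3, seed = 1), "only 2 survive")
  expect_error(threshold_ensemble(generate_spin_ensemble(s, 4, seed = 3),
                                  10, 2, seed = 1), "unscored")

  # 0% removal is a plain uniform subsample of the full ensemble
  all4 <- threshold_ensemble(sp, 0, 4, seed = 9)
  expect_equal(sort(all4$qualities), c(0.1, 0.2, 0.3, 0.4))

  # the quality floor of the surviving pool is non-decreasing along a sweep
  big <- generate_spin_ensemble(s, 100, seed = 21)
  big <- score_ensemble_quality(big, pairwise_euclidean(s))
  floors <- vapply(c(0, 25, 50, 75, 90), function(thr) {
    sub <- threshold_ensemble(big, thr, 5, seed = 2)
    min(big$qualities[big$qualities >= attr(sub, "cutoff")])
  }, numeric(1))
  expect_true(all(diff(floors) >= 0))
})
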