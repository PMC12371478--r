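test_that("inverse-distance weights match closed forms", {
  # two vertices at distance 2, row-normalized: single-neighbour rows
  d2 <- matrix(c(0, 2, 2, 0), 2L)
  w2 <- inverse_distance_weights(d2)
  expect_equal(w2$weights, matrix(c(0, 1, 1, 0), 2L))
  expect_equal(w2$W0, 2)

  # three vertices at mutual distances 1, 2, 2 (un-normalized)
  d3 <- matrix(c(0, 1, 2, 1, 0, 2, 2, 2, 0), 3L)
  w3 <- inverse_distance_weights(d3, row_normalize = FALSE)
  expect_equal(sort(unique(w3$weights[upper.tri(w3$weights)])), c(0.5, 1))
  expect_equal(w3$W0, 4)

  # row-normalized W0 equals the vertex count, rows sum to one
  w3n <- inverse_distance_weights(d3)
  expect_equal(rowSums(w3n$weights), rep(1, 3), tolerance = 1e-12)
  expect_equal(w3n$W0, 3, tolerance = 1e-9)

  dup <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3L)
  expect_error(inverse_distance_weights(dup), "vertices 1 and 2")
})

test_that("standardization uses the population convention", {
  z <- standardize(c(0, 2))
  expect_equal(z$z, c(-1, 1))
  expect_error(standardize(c(1, 1, 1)), "constant")
  u <- stats::rnorm(50, mean = 7, sd = 3)
  z1 <- standardize(u)$z
  expect_equal(mean(z1), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z1^2)), 1, tolerance = 1e-12)
  expect_equal(standardize(z1)$z, z1, tolerance = 1e-12)
})

test_that("global Moran's I captures autocorrelation sign", {
  # unit-spacing ring of 4, alternating values: anti-correlated
  ring <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  W <- inverse_distance_weights(pairwise_euclidean(ring))
  expect_lt(morans_i(c(1, -1, 1, -1), W), 0)

  # smooth gradient on an icosphere: positively autocorrelated
  s <- small_sphere()
  expect_gt(morans_i(s$coordinates[, 1L], small_sphere_W()), 0)

  # affine invariance: I(a u + b) = I(u)
  set.seed(21)
  for (i in 1:10) {
    u <- stats::rnorm(n_vertices(s))
    a <- stats::runif(1, -5, 5)
    if (abs(a) < 0.1) a <- 1
    b <- stats::rnorm(1, sd = 10)
    expect_equal(morans_i(a * u + b, small_sphere_W()),
                 morans_i(u, small_sphere_W()), tolerance = 1e-12)
  }
})

test_that("local Moran's I decomposes the global statistic exactly", {
  s <- small_sphere()
  u <- s$coordinates[, 2L] + stats::rnorm(n_vertices(s), sd = 5)
  for (norm in c(TRUE, FALSE)) {
    W <- inverse_distance_weights(pairwise_euclidean(s), row_normalize = norm)
    li <- local_morans_i(u, W)
    expect_equal(sum(li) / W$W0, morans_i(u, W), tolerance = 1e-12)
    if (norm) expect_equal(mean(li), morans_i(u, W), tolerance = 1e-12)
  }

  # isolated vertex (all-zero weight row) contributes nothing
  w <- matrix(1, 4L, 4L); diag(w) <- 0; w[2L, ] <- 0
  li <- local_morans_i(c(0, 1, 2, 4), spinbench:::new_weight_matrix(w, FALSE))
  expect_identical(li[2L], 0)

  # n = 2 closed form with row-normalized weights
  w2 <- spinbench:::new_weight_matrix(matrix(c(0, 1, 1, 0), 2L), TRUE)
  expect_equal(local_morans_i(c(0, 2), w2), c(-1, -1))
  expect_equal(morans_i(c(0, 2), w2), -1)
})

test_that("delta local Moran's I vanishes for symmetry-preserving spins", {
  s <- small_sphere()
  W <- small_sphere_W()
  u <- s$coordinates[, 1L]
  expect_equal(delta_local_morans_i(u, W, seq_len(n_vertices(s))),
               rep(0, n_vertices(s)))
  expect_error(delta_local_morans_i(u, W, rep(1L, n_vertices(s))),
               "bijection")

  # swapping two vertices whose exchange is an isometry of the point set
  pts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  Wp <- inverse_distance_weights(pairwise_euclidean(pts),
                                 row_normalize = FALSE)
  d <- delta_local_morans_i(c(0.3, -1, 2, 0.5), Wp, c(2L, 1L, 3L, 4L))
  expect_equal(max(abs(d)), 0, tolerance = 1e-12)
})

test_that("Moran scatter coordinates multiply to the local statistics", {
  s <- small_sphere()
  W <- small_sphere_W()
  set.seed(3)
  u <- stats::rnorm(n_vertices(s))
  sc <- moran_scatter(u, W)
  expect_equal(sc$z * sc$lagged_z, local_morans_i(u, W), tolerance = 1e-12)

  perm <- sample(n_vertices(s))
  scd <- moran_scatter(u, W, delta_perm = perm)
  expect_equal(scd$z * scd$lagged_z, delta_local_morans_i(u, W, perm),
               tolerance = 1e-12)
  # one +1 neighbour with row-normalized weights: the lag is that value
  w <- matrix(0, 4L, 4L); w[1L, 2L] <- 1; w[2L, 1L] <- 1
  w[3L, 4L] <- 1; w[4L, 3L] <- 1
  u4 <- c(2, 4, 2, 4)
  sc4 <- moran_scatter(u4, spinbench:::new_weight_matrix(w, TRUE))
  expect_equal(sc4$lagged_z, standardize(u4)$z[c(2L, 1L, 4L, 3L)])

  expect_error(moran_scatter(rep(1, n_vertices(s)), W), "constant")
})

test_that("standardized Moran's I is signed and guarded", {
  s <- small_sphere()
  W <- small_sphere_W()
  spins <- generate_spin_ensemble(s, 50, seed = 14)
  # a coordinate gradient is far more autocorrelated than typical spun noise
  set.seed(8)
  u <- s$coordinates[, 1L] + stats::rnorm(n_vertices(s), sd = 20)
  z <- standardized_moran(u, spins, W)
  expect_type(as.numeric(z), "double")
  expect_equal(attr(z, "empirical"), morans_i(u, W))
  expect_length(attr(z, "surrogate"), 50L)
  expect_equal(as.numeric(z),
               (attr(z, "empirical") - mean(attr(z, "surrogate"))) /
                 stats::sd(attr(z, "surrogate")), tolerance = 1e-12)

  # an ensemble of identical permutations has zero surrogate spread
  ident <- spins
  ident$permutations <- matrix(rep(seq_len(n_vertices(s)), 5),
                               nrow = 5, byrow = TRUE)
  ident$rotations <- array(diag(3), dim = c(3, 3, 5))
  expect_error(standardized_moran(u, ident, W), "constant")
})

test_that("spin quality anti-correlates with Moran deviation on a bumpy pair", {
  pair <- make_bumpy_pair(2, amplitude = 0.25, harmonic_order = 4,
                          radius = 100, seed = 1)
  Dp <- pairwise_euclidean(pair$surface)
  W <- inverse_distance_weights(Dp)
  spins <- generate_spin_ensemble(pair, 200, seed = 33)
  spins <- score_ensemble_quality(spins, Dp)
  m <- field_model(50, n_modes = 256L)
  u <- generate_field(pair$surface, sample_modes(m, 90), m)
  dev <- moran_deviation(u, spins, W)
  expect_lt(stats::cor(spins$qualities, abs(dev$per_spin)), 0)
})
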