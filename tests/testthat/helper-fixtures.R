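# Shared fixtures, built lazily and cached for the whole test run. The
# desk-scale objects (642-vertex meshes, 300-spin ensembles, 100-map field
# ensembles) are shared between the benchmark-style tests so the expensive
# generation happens once.

.fix <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fix, inherits = FALSE)) {
    assign(name, force(expr), envir = .fix)
  }
  get(name, envir = .fix)
}

# canonical seeds for the benchmark fixtures (fixed once, shared everywhere)
SEED_MAPS <- 101L
SEED_SPINS <- 202L
SEED_SWEEP <- 77L
DESK_LENGTHS <- c(5, 25, 50)

small_sphere <- function() cached("small_sphere", make_icosphere(2, radius = 100))

small_sphere_W <- function() cached("small_sphere_W", {
  inverse_distance_weights(pairwise_euclidean(small_sphere()))
})

desk_sphere <- function() cached("desk_sphere", make_icosphere(3, radius = 100))

desk_pair <- function() cached("desk_pair", {
  make_bumpy_pair(3, amplitude = 0.25, harmonic_order = 4, radius = 100,
                  seed = 1)
})

desk_sphere_W <- function() cached("desk_sphere_W", {
  inverse_distance_weights(pairwise_euclidean(desk_sphere()))
})

desk_pair_W <- function() cached("desk_pair_W", {
  inverse_distance_weights(pairwise_euclidean(desk_pair()$surface))
})

desk_sphere_maps <- function() cached("desk_sphere_maps", {
  generate_ensemble(desk_sphere(), DESK_LENGTHS, 100, seed = SEED_MAPS)
})

desk_pair_maps <- function() cached("desk_pair_maps", {
  generate_ensemble(desk_pair()$surface, DESK_LENGTHS, 100, seed = SEED_MAPS)
})

desk_sphere_spins <- function() cached("desk_sphere_spins", {
  generate_spin_ensemble(desk_sphere(), 300, seed = SEED_SPINS)
})

desk_pair_spins <- function() cached("desk_pair_spins", {
  generate_spin_ensemble(desk_pair(), 300, seed = SEED_SPINS)
})

# mean FPR and per-map tables per length for one geometry
desk_fpr <- function(maps_ens, spins) {
  lapply(maps_ens$maps, function(m) fpr_experiment(m, spins)$per_map_fpr)
}

desk_sphere_fpr <- function() cached("desk_sphere_fpr", {
  desk_fpr(desk_sphere_maps(), desk_sphere_spins())
})

desk_pair_fpr <- function() cached("desk_pair_fpr", {
  desk_fpr(desk_pair_maps(), desk_pair_spins())
})

desk_sphere_dev <- function() cached("desk_sphere_dev", {
  lapply(desk_sphere_maps()$maps, function(m) {
    spinbench:::moran_deviation_batch(m, desk_sphere_spins(), desk_sphere_W())
  })
})

desk_pair_dev <- function() cached("desk_pair_dev", {
  lapply(desk_pair_maps()$maps, function(m) {
    spinbench:::moran_deviation_batch(m, desk_pair_spins(), desk_pair_W())
  })
})

# 3000-spin scored ensemble on the bumpy pair, for the removal sweep
desk_big_spins <- function() cached("desk_big_spins", {
  big <- generate_spin_ensemble(desk_pair(), 3000, seed = SEED_SPINS)
  score_ensemble_quality(big, pairwise_euclidean(desk_pair()$surface))
})

# Rodrigues rotation about an axis, used by the symmetry and isometry tests
rotation_about <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3L,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# binomial standard error of a proportion estimated from n Bernoulli trials
binom_se <- function(p, n) sqrt(p * (1 - p) / n)
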