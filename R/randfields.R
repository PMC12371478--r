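# Gaussian-variogram random fields on mesh vertices via the randomization
# (spectral) method: a sum of cosine/sine modes with Gaussian random
# wavevectors reproduces, in expectation, the Gaussian covariance
# sigma^2 * exp(-(s*h/l)^2).

#' Define a Gaussian-variogram field model
#'
#' The model has semivariogram
#' \deqn{\gamma(h) = \sigma^2 \left[1 - e^{-(s h / l)^2}\right],}
#' where `h` is distance in mm, `l` the length parameter controlling the
#' spatial extent of autocorrelation, `sigma2` the sill (process variance),
#' and `s` a unitless rescale factor. The default `s = sqrt(pi)/2` matches
#' the convention of common geostatistics toolboxes for the Gaussian model;
#' `s = 1` recovers the bare exponent `(h/l)^2`.
#'
#' @param length correlation length `l` in mm (`> 0`).
#' @param sigma2 process variance (sill), in map-units squared (`> 0`).
#' @param rescale unitless rescale factor `s` (`> 0`).
#' @param n_modes number of Fourier modes `N` used by the randomization
#'   method (`>= 1`).
#' @return an object of class `field_model`.
#' @examples
#' m <- field_model(length = 25)
#' variogram(c(0, 10, 1e6), m)
#' @export
field_model <- function(length, sigma2 = 1, rescale = sqrt(pi) / 2,
                        n_modes = 1000L) {
  assert_scalar_number(length, "length", lower = .Machine$double.eps)
  assert_scalar_number(sigma2, "sigma2", lower = .Machine$double.eps)
  assert_scalar_number(rescale, "rescale", lower = .Machine$double.eps)
  assert_scalar_number(n_modes, "n_modes", lower = 1)
  structure(
    list(length = length, sigma2 = sigma2, rescale = rescale,
         n_modes = as.integer(n_modes)),
    class = "field_model"
  )
}

#' @export
print.field_model <- function(x, ...) {
  cat(sprintf("<field_model> l = %g mm, sigma2 = %g, s = %g, N = %d\n",
              x$length, x$sigma2, x$rescale, x$n_modes))
  invisible(x)
}

#' Evaluate the Gaussian semivariogram
#'
#' @param h non-negative distances in mm (vectorized).
#' @param model a [field_model()].
#' @return semivariance values in map-units squared: 0 at `h = 0`, rising to
#'   the sill `sigma2` as `h` grows.
#' @export
variogram <- function(h, model) {
  stopifnot(inherits(model, "field_model"))
  if (any(h < 0)) stop("distances `h` must be non-negative", call. = FALSE)
  model$sigma2 * (1 - exp(-(model$rescale * h / model$length)^2))
}

#' Sample the spectral modes of the randomization method
#'
#' Draws `N` wavevectors from the spectral density of the Gaussian covariance
#' and two sets of `N` standard-normal amplitudes. For covariance
#' `sigma^2 exp(-(s h/l)^2)` the spectral measure is isotropic normal with
#' per-component standard deviation `sqrt(2) * s / l`, since
#' `E[cos(k . h)] = exp(-v |h|^2 / 2)` for `k ~ N(0, v I3)` and
#' `v = 2 s^2 / l^2` matches the exponent.
#'
#' Internally the wavevectors are stored as standard-normal draws `k0` scaled
#' by `sqrt(2) s / l` at evaluation time, so the same seed yields modes at
#' different lengths that share every underlying random variate — the sharing
#' used when comparing ensembles across autocorrelation levels.
#'
#' @param model a [field_model()].
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return an object of class `spectral_modes` with elements `k` (`N x 3`
#'   wavevectors, 1/mm), `z1`, `z2` (length-`N` standard normals), `k0`
#'   (the unscaled wavevector draws) and `seed`.
#' @export
sample_modes <- function(model, seed) {
  stopifnot(inherits(model, "field_model"))
  n <- model$n_modes
  draws <- with_seed(seed, {
    list(
      z1 = stats::rnorm(n),
      z2 = stats::rnorm(n),
      k0 = matrix(stats::rnorm(3L * n), nrow = n, ncol = 3L)
    )
  })
  k_sd <- sqrt(2) * model$rescale / model$length
  structure(
    list(k = draws$k0 * k_sd, z1 = draws$z1, z2 = draws$z2,
         k0 = draws$k0, seed = as.integer(seed)),
    class = "spectral_modes"
  )
}

#' Evaluate a random field at vertex positions
#'
#' Computes the randomization-method field
#' \deqn{u(x) = \sqrt{\sigma^2 / N} \sum_{i=1}^{N}
#'   \left[Z_{1,i} \cos(k_i \cdot x) + Z_{2,i} \sin(k_i \cdot x)\right]}
#' at every row of `coords`. The prefactor `sqrt(sigma2 / N)` is the unique
#' choice for which `Var[u(x)] = sigma2`.
#'
#' @param coords numeric matrix of positions (rows; mm), or a
#'   [surface_mesh()].
#' @param modes a [sample_modes()] result.
#' @param model the [field_model()] the modes were sampled for.
#' @return numeric per-vertex map.
#' @export
generate_field <- function(coords, modes, model) {
  stopifnot(inherits(modes, "spectral_modes"), inherits(model, "field_model"))
  if (inherits(coords, "surface_mesh")) coords <- coords$coordinates
  coords <- as.matrix(coords)
  if (any(!is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  phase <- coords %*% t(modes$k)            # n_vertices x N
  drop(sqrt(model$sigma2 / model$n_modes) *
         (cos(phase) %*% modes$z1 + sin(phase) %*% modes$z2))
}

#' Generate an ensemble of random fields across autocorrelation lengths
#'
#' Produces `n_maps` fields at each requested length. With
#' `shared_draws = TRUE` (default) the normal amplitudes and the underlying
#' wavevector variates are reused across lengths, so that map `m` at one
#' length differs from map `m` at another length only through the variogram
#' scale — the construction used to compare a test's behaviour across
#' autocorrelation levels on identical randomness.
#'
#' @param mesh a [surface_mesh()] (or coordinate matrix) to evaluate on.
#' @param lengths numeric vector of correlation lengths in mm.
#' @param n_maps number of maps per length.
#' @param seed master seed; per-map substream seeds are derived from it.
#' @param shared_draws reuse random draws across lengths (default `TRUE`).
#' @param sigma2,rescale,n_modes forwarded to [field_model()].
#' @return an object of class `field_ensemble`: a list with `maps` (a list
#'   indexed by length name, each a `n_vertices x n_maps` matrix), `lengths`,
#'   `model_params`, `seed`, and `map_seeds`.
#' @export
generate_ensemble <- function(mesh, lengths, n_maps, seed,
                              shared_draws = TRUE, sigma2 = 1,
                              rescale = sqrt(pi) / 2, n_modes = 1000L) {
  if (n_maps < 1L) stop("`n_maps` must be >= 1", call. = FALSE)
  coords <- if (inherits(mesh, "surface_mesh")) mesh$coordinates else as.matrix(mesh)
  if (shared_draws) {
    map_seeds <- matrix(rep(derive_seeds(seed, n_maps), length(lengths)),
                        nrow = n_maps)
  } else {
    map_seeds <- matrix(derive_seeds(seed, n_maps * length(lengths)),
                        nrow = n_maps)
  }
  maps <- vector("list", length(lengths))
  names(maps) <- as.character(lengths)
  for (j in seq_along(lengths)) {
    model <- field_model(lengths[j], sigma2 = sigma2, rescale = rescale,
                         n_modes = n_modes)
    out <- matrix(0, nrow = nrow(coords), ncol = n_maps)
    for (m in seq_len(n_maps)) {
      out[, m] <- generate_field(coords, sample_modes(model, map_seeds[m, j]),
                                 model)
    }
    maps[[j]] <- out
  }
  structure(
    list(maps = maps, lengths = lengths,
         model_params = list(sigma2 = sigma2, rescale = rescale,
                             n_modes = as.integer(n_modes)),
         seed = as.integer(seed), map_seeds = map_seeds,
         shared_draws = shared_draws),
    class = "field_ensemble"
  )
}

#' @export
print.field_ensemble <- function(x, ...) {
  cat(sprintf(
    "<field_ensemble> %d maps x %d lengths (%s mm), %d vertices, seed %d\n",
    ncol(x$maps[[1L]]), length(x$lengths),
    paste(x$lengths, collapse = ", "), nrow(x$maps[[1L]]), x$seed))
  invisible(x)
}

#' Export a field ensemble to per-map CSV files
#'
#' Writes one single-column CSV per (length, map) plus a JSON manifest
#' recording the model parameters and seeds.
#'
#' @param ensemble a [generate_ensemble()] result.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_ensemble_csv <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "field_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ln in names(ensemble$maps)) {
    m <- ensemble$maps[[ln]]
    for (j in seq_len(ncol(m))) {
      write_map_csv(m[, j],
                    file.path(dir, sprintf("map_l%s_%04d.csv", ln, j)))
    }
  }
  manifest <- file.path(dir, "ensemble.json")
  jsonlite::write_json(
    list(lengths = ensemble$lengths, n_maps = ncol(ensemble$maps[[1L]]),
         model = ensemble$model_params, seed = ensemble$seed,
         shared_draws = ensemble$shared_draws),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
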