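# Spatial weights and Moran statistics: global and local Moran's I, the
# rotation-distortion decomposition of local Moran differences, Moran
# scatterplot coordinates, and the standardized Moran's I against a spin
# ensemble.

#' Build inverse-distance spatial weights
#'
#' Off-diagonal weights are `1 / d_ij`; the diagonal is zero. With
#' `row_normalize = TRUE` (the convention used throughout the spin-test
#' diagnostics) each row is divided by its sum, so the total weight `W0`
#' equals the vertex count.
#'
#' @param D a [pairwise_euclidean()] / [pairwise_geodesic()] result, or a
#'   plain symmetric distance matrix.
#' @param row_normalize divide each row by its sum (default `TRUE`).
#' @return an object of class `weight_matrix` with elements `weights`
#'   (dense matrix), `W0` (sum of all weights) and `row_normalized`.
#' @export
inverse_distance_weights <- function(D, row_normalize = TRUE) {
  d <- if (inherits(D, "distance_matrix")) D$values else as.matrix(D)
  n <- nrow(d)
  off <- d + diag(Inf, n)
  if (any(off <= 0)) {
    bad <- sort(which(off <= 0, arr.ind = TRUE)[1L, ])
    stop(sprintf(
      "zero off-diagonal distance between vertices %d and %d (duplicate vertices?)",
      bad[1L], bad[2L]), call. = FALSE)
  }
  w <- 1 / d
  diag(w) <- 0
  if (row_normalize) {
    w <- w / rowSums(w)
  }
  new_weight_matrix(w, row_normalized = row_normalize)
}

new_weight_matrix <- function(w, row_normalized) {
  structure(list(weights = w, W0 = sum(w), row_normalized = row_normalized),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf("<weight_matrix> %d x %d, W0 = %g, row_normalized = %s\n",
              nrow(x$weights), ncol(x$weights), x$W0, x$row_normalized))
  invisible(x)
}

#' Standardize a map to zero mean and unit population variance
#'
#' Uses the population (divide-by-n) standard deviation, under which
#' `sum(z^2) = n` and the weighted cross-product form of Moran's I agrees
#' with the textbook definition.
#'
#' @param u numeric per-vertex map with nonzero variance.
#' @return a list of class `standardized_map` with `z` (standardized values),
#'   `mean` and `sd` (population convention).
#' @export
standardize <- function(u) {
  u <- as.numeric(u)
  if (length(u) < 2L) stop("need at least 2 values", call. = FALSE)
  if (any(!is.finite(u))) stop("map values must be finite", call. = FALSE)
  m <- mean(u)
  s <- sqrt(mean((u - m)^2))
  if (s == 0) {
    stop("map is constant: Moran's I is undefined for zero-variance maps",
         call. = FALSE)
  }
  structure(list(z = (u - m) / s, mean = m, sd = s),
            class = "standardized_map")
}

as_weight_matrix <- function(W) {
  if (inherits(W, "weight_matrix")) return(W)
  w <- as.matrix(W)
  new_weight_matrix(w, row_normalized = all(abs(rowSums(w) - 1) < 1e-9))
}

check_map_weights <- function(u, W) {
  if (length(u) != nrow(W$weights)) {
    stop("map length (", length(u), ") does not match weight matrix size (",
         nrow(W$weights), ")", call. = FALSE)
  }
}

#' Global Moran's I
#'
#' Computes `I = (1/W0) * sum_ij w_ij z_i z_j` with `z` the standardized map.
#' `I > 0` indicates spatial autocorrelation (nearby vertices carry similar
#' values), `I < 0` anti-correlation; under random permutation of the values
#' its expectation is `-1/(n-1)`.
#'
#' @param u numeric per-vertex map.
#' @param W a [inverse_distance_weights()] result (or plain weight matrix).
#' @return a single numeric value.
#' @export
morans_i <- function(u, W) {
  W <- as_weight_matrix(W)
  check_map_weights(u, W)
  z <- standardize(u)$z
  drop(crossprod(z, W$weights %*% z)) / W$W0
}

#' Local Moran's I
#'
#' Per-vertex decomposition `I_i = z_i * sum_j w_ij z_j`. The global
#' statistic is recovered as `(1/W0) * sum_i I_i`; with row-normalized
#' weights this is simply the mean of the local values.
#'
#' @inheritParams morans_i
#' @return numeric per-vertex vector of local Moran's I values.
#' @export
local_morans_i <- function(u, W) {
  W <- as_weight_matrix(W)
  check_map_weights(u, W)
  z <- standardize(u)$z
  z * drop(W$weights %*% z)
}

# Weight matrix seen by the values after a spin: with spun map
# u'_i = u[perm[i]], the weights relocate as w'_{ab} = w[inv(a), inv(b)].
spun_weights <- function(W, perm) {
  inv <- invert_permutation(perm)
  W$weights[inv, inv, drop = FALSE]
}

invert_permutation <- function(perm) {
  n <- length(perm)
  perm <- as.integer(perm)
  if (anyNA(perm) || any(perm < 1L) || any(perm > n) ||
      anyDuplicated(perm) > 0L) {
    stop("index map is not a bijection on 1..", n, call. = FALSE)
  }
  inv <- integer(n)
  inv[perm] <- seq_len(n)
  inv
}

#' Difference in local Moran's I induced by a spin
#'
#' For a spin stored as a permutation `perm` (spun map
#' `u'[i] = u[perm[i]]`), computes the per-vertex decomposition
#' `delta_I_i = z_i * sum_j z_j (w_ij - w'_ij)`, where `w'` is the original
#' weight matrix re-indexed through the inverse permutation — the weights
#' "seen" by the map values after the spin. The normalized sum
#' `(1/W0) * sum_i delta_I_i` equals the difference between the global
#' Moran's I of the original and of the spun map.
#'
#' @param u numeric per-vertex map.
#' @param W weight matrix of the original surface.
#' @param perm integer vertex permutation (a true bijection).
#' @return numeric per-vertex vector of local Moran differences.
#' @export
delta_local_morans_i <- function(u, W, perm) {
  W <- as_weight_matrix(W)
  check_map_weights(u, W)
  z <- standardize(u)$z
  dw <- W$weights - spun_weights(W, perm)
  z * drop(dw %*% z)
}

#' Moran scatterplot coordinates
#'
#' Returns the per-vertex pairs (standardized value, spatially lagged
#' standardized value) whose products are the local Moran's I values. When
#' `delta_perm` is supplied, the lag is computed against the *difference*
#' between the original weights and the spun weights, so the products give
#' the per-vertex change in local Moran's I under that spin.
#'
#' @param u numeric per-vertex map.
#' @param W weight matrix.
#' @param delta_perm optional vertex permutation; when given, the scatter
#'   shows the rotation-distortion decomposition.
#' @return a data.frame with columns `z` and `lagged_z`.
#' @export
moran_scatter <- function(u, W, delta_perm = NULL) {
  W <- as_weight_matrix(W)
  check_map_weights(u, W)
  z <- standardize(u)$z
  wmat <- if (is.null(delta_perm)) W$weights else W$weights - spun_weights(W, delta_perm)
  data.frame(z = z, lagged_z = drop(wmat %*% z))
}

# Global Moran's I of every column of a matrix of maps (each standardized
# independently), against a fixed weight matrix. One BLAS call per batch.
morans_i_batch <- function(maps, W) {
  W <- as_weight_matrix(W)
  maps <- as.matrix(maps)
  check_map_weights(maps[, 1L], W)
  z <- scale_population(maps)
  colSums(z * (W$weights %*% z)) / W$W0
}

# Column-wise population standardization; errors on constant columns.
scale_population <- function(m) {
  mu <- colMeans(m)
  zc <- sweep(m, 2L, mu)
  sd_pop <- sqrt(colMeans(zc^2))
  if (any(sd_pop == 0)) {
    stop("constant map encountered (zero variance)", call. = FALSE)
  }
  sweep(zc, 2L, sd_pop, "/")
}

#' Standardized Moran's I of a map against its spin nulls
#'
#' Computes `zI = (I_emp - mean(I_spun)) / sd(I_spun)` where the surrogate
#' Moran's I values come from applying each spin of the ensemble to the map
#' and measuring spatial autocorrelation with the fixed weight matrix of the
#' original surface. Large `|zI|` means the spin procedure systematically
#' alters the map's autocorrelation.
#'
#' @param u numeric per-vertex map.
#' @param spins a [generate_spin_ensemble()] result.
#' @param W weight matrix of the original surface.
#' @return a single numeric z-score, with attributes `empirical` (the map's
#'   Moran's I) and `surrogate` (per-spin Moran's I values).
#' @export
standardized_moran <- function(u, spins, W) {
  stopifnot(inherits(spins, "spin_ensemble"))
  W <- as_weight_matrix(W)
  check_map_weights(u, W)
  i_emp <- morans_i(u, W)
  spun <- apply_spins(u, spins)
  i_spun <- morans_i_batch(spun, W)
  s <- stats::sd(i_spun)
  if (s == 0) {
    stop("surrogate Moran's I values are constant (degenerate spin ensemble)",
         call. = FALSE)
  }
  structure((i_emp - mean(i_spun)) / s,
            empirical = i_emp, surrogate = i_spun)
}
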