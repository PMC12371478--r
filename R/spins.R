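# The spin procedure: Haar-uniform rotation sampling, nearest-neighbour
# vertex matching, ensemble generation, per-spin quality scoring, and
# quality-thresholded subsampling.

#' Sample a uniformly random 3-D rotation
#'
#' Draws a rotation from the Haar (rotation-invariant) measure on SO(3):
#' QR-factorize a 3x3 standard-normal matrix, fix the sign ambiguity by
#' multiplying each column of Q by the sign of the corresponding diagonal
#' entry of R (giving Haar on O(3)), and if the determinant is -1 negate the
#' last column to land in SO(3).
#'
#' Consumes the current RNG state; seed beforehand for reproducibility.
#'
#' @return a 3x3 rotation matrix (`R^T R = I`, `det R = +1`).
#' @export
sample_rotation <- function() {
  qr_fac <- qr(matrix(stats::rnorm(9L), 3L, 3L))
  q <- qr.Q(qr_fac)
  r <- qr.R(qr_fac)
  sgn <- sign(diag(r))
  sgn[sgn == 0] <- 1
  q <- q * rep(sgn, each = 3L)
  if (det(q) < 0) q[, 3L] <- -q[, 3L]
  q
}

# Sphere coordinates recentred to the centroid (rotations act about the
# origin; meshes loaded from files may be offset).
sphere_coords <- function(x) {
  coords <- if (inherits(x, "surface_pair")) {
    x$sphere$coordinates
  } else if (inherits(x, "surface_mesh")) {
    x$coordinates
  } else {
    stop("need a `surface_pair` or `surface_mesh`", call. = FALSE)
  }
  sweep(coords, 2L, colMeans(coords))
}

#' Build one spin from a rotation
#'
#' Rotates the sphere vertices and matches each *original* vertex to its
#' nearest rotated vertex (Euclidean metric, ties broken by lowest vertex
#' index). The result is an index map `perm` under which the spun map is
#' `u_spun[i] = u[perm[i]]`: every output vertex receives a value, but
#' sources may repeat, so `perm` is not necessarily a bijection.
#'
#' @param x a [surface_pair()] (its sphere member is used) or a spherical
#'   [surface_mesh()].
#' @param rotation a 3x3 rotation matrix from [sample_rotation()].
#' @return integer vector of source vertex indices, one per vertex.
#' @export
build_spin <- function(x, rotation) {
  coords <- sphere_coords(x)
  rotated <- coords %*% t(rotation)
  nn_match(coords, rotated)
}

# For each row of `query`, index of the nearest row of `ref` (lowest index
# wins ties). Chunked so the cross-distance block stays small.
nn_match <- function(query, ref, chunk = 2048L) {
  n <- nrow(query)
  ref_sq <- rowSums(ref^2)
  out <- integer(n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    # squared distances up to the constant |query|^2 term
    d2 <- sweep(-2 * query[idx, , drop = FALSE] %*% t(ref), 2L, ref_sq, "+")
    out[idx] <- max.col(-d2, ties.method = "first")
  }
  out
}

#' Generate a spin ensemble
#'
#' Draws `n_spins` independent Haar-uniform rotations and converts each to a
#' vertex index map by nearest-neighbour matching on the (recentred) sphere.
#'
#' @param x a [surface_pair()] or spherical [surface_mesh()].
#' @param n_spins number of spins (`>= 1`).
#' @param seed integer seed; the ensemble is deterministic given the seed.
#' @return an object of class `spin_ensemble`: `permutations`
#'   (`n_spins x n_vertices` integer matrix), `rotations`
#'   (`3 x 3 x n_spins` array), `qualities` (`NULL` until scored),
#'   and provenance (`seed`, `fingerprint`).
#' @export
generate_spin_ensemble <- function(x, n_spins, seed) {
  if (n_spins < 1L) stop("`n_spins` must be >= 1", call. = FALSE)
  mesh <- if (inherits(x, "surface_pair")) x$sphere else x
  coords <- sphere_coords(x)
  rotations <- array(NA_real_, dim = c(3L, 3L, n_spins))
  perms <- matrix(NA_integer_, nrow = n_spins, ncol = nrow(coords))
  with_seed(seed, {
    for (s in seq_len(n_spins)) {
      rot <- sample_rotation()
      rotations[, , s] <- rot
      perms[s, ] <- nn_match(coords, coords %*% t(rot))
    }
  })
  structure(
    list(permutations = perms, rotations = rotations, qualities = NULL,
         seed = as.integer(seed), fingerprint = mesh_fingerprint(mesh),
         quality_provenance = NULL),
    class = "spin_ensemble"
  )
}

#' @export
print.spin_ensemble <- function(x, ...) {
  cat(sprintf("<spin_ensemble> %d spins on %d vertices, seed %d, %s\n",
              nrow(x$permutations), ncol(x$permutations), x$seed,
              if (is.null(x$qualities)) "unscored" else "scored"))
  invisible(x)
}

#' Number of spins in an ensemble
#' @param spins a `spin_ensemble`.
#' @return integer spin count.
#' @export
n_spins <- function(spins) {
  stopifnot(inherits(spins, "spin_ensemble"))
  nrow(spins$permutations)
}

#' Apply every spin of an ensemble to a map
#'
#' @param u numeric per-vertex map.
#' @param spins a [generate_spin_ensemble()] result.
#' @return a `n_vertices x n_spins` matrix of spun maps.
#' @export
apply_spins <- function(u, spins) {
  stopifnot(inherits(spins, "spin_ensemble"))
  u <- as.numeric(u)
  if (length(u) != ncol(spins$permutations)) {
    stop("map length does not match the ensemble's vertex count", call. = FALSE)
  }
  matrix(u[t(spins$permutations)], nrow = length(u))
}

#' Score the quality of one spin
#'
#' Quality is the Pearson correlation between the upper-triangle entries of
#' the original surface distance matrix and of the same matrix re-indexed
#' through the spin (`D[i, j] -> D[perm[i], perm[j]]`). An identity spin
#' scores 1; spins that scramble distance relationships score lower. Scored
#' against the *cortical surface* distances, this measures how much the
#' full sphere-rotate-project cycle distorted the map's geometry.
#'
#' @param perm integer vertex index map from [build_spin()].
#' @param D distance matrix of the cortical surface ([pairwise_euclidean()]
#'   or [pairwise_geodesic()] result, or plain matrix).
#' @param vertex_subset optional integer vector of vertices to restrict the
#'   correlation to (used for large meshes).
#' @return a scalar in `[-1, 1]`.
#' @export
score_quality <- function(perm, D, vertex_subset = NULL) {
  d <- if (inherits(D, "distance_matrix")) D$values else as.matrix(D)
  if (nrow(d) < 3L) stop("need at least 3 vertices to score a spin",
                         call. = FALSE)
  idx <- if (is.null(vertex_subset)) seq_len(nrow(d)) else as.integer(vertex_subset)
  ut <- upper.tri(matrix(0, length(idx), length(idx)))
  orig <- d[idx, idx][ut]
  spun <- d[perm[idx], perm[idx]][ut]
  stats::cor(orig, spun)
}

#' Score every spin of an ensemble
#'
#' Adds a `qualities` vector to the ensemble. For meshes larger than
#' `max_vertices`, the distance-matrix correlation is computed on a seeded
#' uniform vertex subsample (recorded in the ensemble's provenance).
#'
#' @param spins a [generate_spin_ensemble()] result.
#' @param D cortical-surface distance matrix.
#' @param max_vertices largest vertex count scored on the full matrix
#'   (default 5000).
#' @param seed seed for the vertex subsample (only used when subsampling).
#' @return the ensemble with `qualities` filled in.
#' @export
score_ensemble_quality <- function(spins, D, max_vertices = 5000L, seed = 1L) {
  stopifnot(inherits(spins, "spin_ensemble"))
  d <- if (inherits(D, "distance_matrix")) D$values else as.matrix(D)
  n <- ncol(spins$permutations)
  if (nrow(d) != n) {
    stop("distance matrix size does not match the ensemble's vertex count",
         call. = FALSE)
  }
  subset <- NULL
  if (n > max_vertices) {
    subset <- sort(with_seed(seed, sample.int(n, max_vertices)))
  }
  spins$qualities <- vapply(
    seq_len(n_spins(spins)),
    function(s) score_quality(spins$permutations[s, ], d, subset),
    numeric(1)
  )
  spins$quality_provenance <- list(
    subsampled = !is.null(subset),
    n_scored = if (is.null(subset)) n else length(subset),
    seed = as.integer(seed)
  )
  spins
}

subset_ensemble <- function(spins, keep) {
  spins$permutations <- spins$permutations[keep, , drop = FALSE]
  spins$rotations <- spins$rotations[, , keep, drop = FALSE]
  if (!is.null(spins$qualities)) spins$qualities <- spins$qualities[keep]
  spins
}

#' Remove low-quality spins and subsample the survivors
#'
#' Drops the lowest-quality `removal_percent` of spins (percentile cut on
#' the quality distribution; ties at the cutoff survive) and then samples
#' `n_sample` spins uniformly without replacement from the survivors, so
#' that null ensembles at different thresholds have equal size.
#'
#' @param spins a scored ensemble (see [score_ensemble_quality()]).
#' @param removal_percent percentage of lowest-quality spins to remove,
#'   in `[0, 100)`.
#' @param n_sample number of spins to draw from the survivors.
#' @param seed seed for the subsample.
#' @return a `spin_ensemble` of `n_sample` spins; the quality cutoff is
#'   attached as attribute `cutoff`.
#' @export
threshold_ensemble <- function(spins, removal_percent, n_sample, seed) {
  stopifnot(inherits(spins, "spin_ensemble"))
  if (is.null(spins$qualities)) {
    stop("ensemble is unscored: run score_ensemble_quality() first",
         call. = FALSE)
  }
  assert_scalar_number(removal_percent, "removal_percent", lower = 0, upper = 100)
  q <- spins$qualities
  cutoff <- if (removal_percent == 0) {
    -Inf
  } else {
    stats::quantile(q, removal_percent / 100, names = FALSE)
  }
  survivors <- which(q >= cutoff)
  if (n_sample > length(survivors)) {
    stop("cannot sample ", n_sample, " spins: only ", length(survivors),
         " survive ", removal_percent, "% removal", call. = FALSE)
  }
  keep <- sort(with_seed(seed, sample(survivors, n_sample)))
  out <- subset_ensemble(spins, keep)
  attr(out, "cutoff") <- cutoff
  out
}

#' Persist a spin ensemble to a directory of text files
#'
#' Writes `permutations.csv` (one row per spin, 1-based vertex indices),
#' `rotations.csv` (one row per spin, the 3x3 matrix in column-major order),
#' optionally `qualities.csv`, and a JSON manifest with seed and mesh
#' fingerprint.
#'
#' @param spins a `spin_ensemble`.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_spin_ensemble <- function(spins, dir) {
  stopifnot(inherits(spins, "spin_ensemble"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(spins$permutations, file.path(dir, "permutations.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  rot <- t(apply(spins$rotations, 3L, identity))
  utils::write.table(format(rot, digits = 17),
                     file.path(dir, "rotations.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  if (!is.null(spins$qualities)) {
    write_qualities_csv(spins, file.path(dir, "qualities.csv"))
  }
  manifest <- file.path(dir, "spins.json")
  jsonlite::write_json(
    list(n_spins = n_spins(spins), n_vertices = ncol(spins$permutations),
         seed = spins$seed, fingerprint = spins$fingerprint,
         scored = !is.null(spins$qualities),
         quality_provenance = spins$quality_provenance),
    manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a spin ensemble written by [write_spin_ensemble()]
#'
#' @param dir directory containing `permutations.csv`, `rotations.csv`,
#'   `spins.json` and optionally `qualities.csv`.
#' @return a `spin_ensemble`.
#' @export
read_spin_ensemble <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "spins.json"),
                              simplifyVector = TRUE)
  perms <- as.matrix(utils::read.table(file.path(dir, "permutations.csv"),
                                       sep = ",", colClasses = "integer"))
  dimnames(perms) <- NULL
  rot_rows <- as.matrix(utils::read.table(file.path(dir, "rotations.csv"),
                                          sep = ","))
  rotations <- array(NA_real_, dim = c(3L, 3L, nrow(rot_rows)))
  for (s in seq_len(nrow(rot_rows))) {
    rotations[, , s] <- matrix(as.numeric(rot_rows[s, ]), 3L, 3L)
  }
  qual <- NULL
  qpath <- file.path(dir, "qualities.csv")
  if (file.exists(qpath)) qual <- utils::read.csv(qpath)$quality
  structure(
    list(permutations = perms, rotations = rotations, qualities = qual,
         seed = as.integer(meta$seed), fingerprint = meta$fingerprint,
         quality_provenance = meta$quality_provenance),
    class = "spin_ensemble"
  )
}

#' Export spin qualities to CSV
#'
#' @param spins a scored ensemble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qualities_csv <- function(spins, path) {
  stopifnot(inherits(spins, "spin_ensemble"))
  if (is.null(spins$qualities)) stop("ensemble is unscored", call. = FALSE)
  utils::write.csv(
    data.frame(spin = seq_along(spins$qualities), quality = spins$qualities),
    path, row.names = FALSE)
  invisible(path)
}
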