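# Surface meshes: data types, synthetic fixtures, and vertex distances.

#' Construct a triangulated surface mesh
#'
#' A `surface_mesh` holds per-vertex coordinates (in mm) and a triangle list.
#' Triangle indices are 1-based, following the R convention; the file readers
#' and writers translate to the 0-based indexing used on disk.
#'
#' @param coordinates numeric matrix with one row per vertex and 3 columns
#'   (x, y, z in mm).
#' @param triangles integer matrix with one row per triangle and 3 columns of
#'   1-based vertex indices.
#' @param check_connected if `TRUE` (default), verify that the mesh edge graph
#'   is a single connected component.
#' @return an object of class `surface_mesh` with elements `coordinates` and
#'   `triangles`.
#' @examples
#' m <- make_icosphere(0, radius = 1)
#' n_vertices(m)
#' @export
surface_mesh <- function(coordinates, triangles, check_connected = TRUE) {
  coordinates <- unname(as.matrix(coordinates))
  storage.mode(coordinates) <- "double"
  triangles <- unname(as.matrix(triangles))
  storage.mode(triangles) <- "integer"
  if (ncol(coordinates) != 3L) {
    stop("`coordinates` must have 3 columns (x, y, z)", call. = FALSE)
  }
  if (ncol(triangles) != 3L) {
    stop("`triangles` must have 3 columns", call. = FALSE)
  }
  nv <- nrow(coordinates)
  if (nv < 4L) {
    stop("a surface mesh needs at least 4 vertices", call. = FALSE)
  }
  if (any(!is.finite(coordinates))) {
    stop("vertex coordinates must be finite", call. = FALSE)
  }
  if (any(triangles < 1L) || any(triangles > nv)) {
    stop("triangle indices out of range [1, ", nv, "]", call. = FALSE)
  }
  degen <- triangles[, 1L] == triangles[, 2L] |
    triangles[, 1L] == triangles[, 3L] |
    triangles[, 2L] == triangles[, 3L]
  if (any(degen)) {
    stop("degenerate triangles (repeated vertex) at rows: ",
         paste(utils::head(which(degen), 5L), collapse = ", "), call. = FALSE)
  }
  mesh <- structure(
    list(coordinates = coordinates, triangles = triangles),
    class = "surface_mesh"
  )
  if (check_connected) {
    comp <- mesh_components(mesh)
    if (comp$no > 1L) {
      stop("mesh is not connected: ", comp$no, " components with sizes ",
           paste(comp$csize, collapse = ", "), call. = FALSE)
    }
  }
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$coordinates), nrow(x$triangles)))
  invisible(x)
}

#' Number of vertices of a mesh
#' @param mesh a `surface_mesh`.
#' @return integer vertex count.
#' @export
n_vertices <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nrow(mesh$coordinates)
}

# Unique undirected edges of the triangulation, one row per edge.
mesh_edges <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1L, 2L)], tri[, c(2L, 3L)], tri[, c(1L, 3L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}

mesh_graph <- function(mesh) {
  e <- mesh_edges(mesh)
  g <- igraph::make_graph(t(e), n = n_vertices(mesh), directed = FALSE)
  len <- sqrt(rowSums((mesh$coordinates[e[, 1L], , drop = FALSE] -
                         mesh$coordinates[e[, 2L], , drop = FALSE])^2))
  igraph::E(g)$weight <- len
  g
}

mesh_components <- function(mesh) {
  comp <- igraph::components(mesh_graph(mesh))
  list(no = comp$no, csize = as.integer(comp$csize))
}

#' Pair a cortical-like surface with its spherical projection
#'
#' The two meshes must share vertex indexing and connectivity: vertex `i` of
#' `surface` projects to vertex `i` of `sphere`. Every sphere vertex must lie
#' on the sphere of the stated radius (relative tolerance `1e-9`).
#'
#' @param surface a `surface_mesh` playing the cortical ("pial") role.
#' @param sphere a `surface_mesh` whose vertices lie on a common sphere.
#' @param radius radius of the sphere in mm; if `NULL`, taken as the mean
#'   vertex distance from the sphere's centroid.
#' @return an object of class `surface_pair`.
#' @export
surface_pair <- function(surface, sphere, radius = NULL) {
  stopifnot(inherits(surface, "surface_mesh"), inherits(sphere, "surface_mesh"))
  if (n_vertices(surface) != n_vertices(sphere)) {
    stop("surface and sphere must have identical vertex counts", call. = FALSE)
  }
  if (!identical(surface$triangles, sphere$triangles)) {
    stop("surface and sphere must share an identical triangle list",
         call. = FALSE)
  }
  ctr <- colMeans(sphere$coordinates)
  r_i <- sqrt(rowSums(sweep(sphere$coordinates, 2L, ctr)^2))
  if (is.null(radius)) radius <- mean(r_i)
  assert_scalar_number(radius, "radius", lower = 0)
  if (max(abs(r_i - radius)) > 1e-9 * radius) {
    stop(sprintf(
      "sphere vertices deviate from radius %g by up to %g (tolerance %g)",
      radius, max(abs(r_i - radius)), 1e-9 * radius), call. = FALSE)
  }
  structure(
    list(surface = surface, sphere = sphere, radius = radius),
    class = "surface_pair"
  )
}

#' @export
print.surface_pair <- function(x, ...) {
  cat(sprintf("<surface_pair> %d vertices, sphere radius %.6g mm\n",
              n_vertices(x$sphere), x$radius))
  invisible(x)
}

# Base icosahedron with unit circumradius.
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(v = v, f = f)
}

#' Build an icosphere mesh
#'
#' Subdivides an icosahedron `subdivisions` times (each triangle split into
#' four through its edge midpoints) and projects all vertices onto the sphere
#' of the requested radius. The vertex count is `10 * 4^s + 2`.
#'
#' @param subdivisions non-negative integer number of subdivision rounds
#'   (at most 7, guarding against accidental multi-million-vertex meshes).
#' @param radius sphere radius in mm.
#' @return a `surface_mesh` whose vertices all lie at distance `radius` from
#'   the origin.
#' @examples
#' s <- make_icosphere(2, radius = 100)
#' n_vertices(s)  # 162
#' @export
make_icosphere <- function(subdivisions, radius = 1) {
  assert_scalar_number(subdivisions, "subdivisions", lower = 0, upper = 7)
  if (subdivisions != round(subdivisions)) {
    stop("`subdivisions` must be an integer", call. = FALSE)
  }
  assert_scalar_number(radius, "radius", lower = 0)
  base <- icosahedron()
  v <- base$v
  f <- base$f
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    # midpoint cache keyed on the (ordered) edge
    key <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
    e1 <- key(f[, 1L], f[, 2L]); e2 <- key(f[, 2L], f[, 3L])
    e3 <- key(f[, 1L], f[, 3L])
    all_keys <- unique(c(e1, e2, e3))
    idx_of <- function(k) nv + match(k, all_keys)
    a <- all_keys %/% (nv + 1); b <- all_keys %% (nv + 1)
    mids <- (v[a, , drop = FALSE] + v[b, , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m1 <- idx_of(e1); m2 <- idx_of(e2); m3 <- idx_of(e3)
    f <- rbind(
      cbind(f[, 1L], m1, m3),
      cbind(f[, 2L], m2, m1),
      cbind(f[, 3L], m3, m2),
      cbind(m1, m2, m3)
    )
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  surface_mesh(v, f, check_connected = FALSE)
}

# Real spherical harmonics Y_lm evaluated at unit direction vectors.
# Returns a matrix with one column per (l, m) basis function, l = 1..order.
real_sph_harm_basis <- function(dirs, order) {
  theta <- acos(pmin(1, pmax(-1, dirs[, 3L])))
  phi <- atan2(dirs[, 2L], dirs[, 1L])
  ct <- cos(theta)
  cols <- list()
  for (l in seq_len(order)) {
    P <- pracma::legendre(l, ct)           # (l+1) x n, rows m = 0..l
    if (is.null(dim(P))) P <- matrix(P, ncol = 1L)
    for (m in 0:l) {
      nrm <- sqrt((2 * l + 1) / (4 * pi) * factorial(l - m) / factorial(l + m))
      if (m == 0L) {
        cols[[length(cols) + 1L]] <- nrm * P[1L, ]
      } else {
        cols[[length(cols) + 1L]] <- sqrt(2) * nrm * P[m + 1L, ] * cos(m * phi)
        cols[[length(cols) + 1L]] <- sqrt(2) * nrm * P[m + 1L, ] * sin(m * phi)
      }
    }
  }
  do.call(cbind, cols)
}

#' Generate a matched sphere / bumpy-surface mesh pair
#'
#' Emulates the geometric situation of the spin test: a folded cortical-like
#' surface and its spherical projection with 1:1 vertex correspondence. The
#' sphere is an icosphere; the surface shares its connectivity, with each
#' vertex displaced radially to `radius * (1 + amplitude * f)`, where `f` is a
#' smooth zero-mean random combination of real spherical harmonics of degree
#' 1 to `harmonic_order`, rescaled so that `max |f| = 1`. Normalizing surface
#' vertices back onto the sphere recovers the sphere exactly, mirroring how a
#' pial surface maps onto its spherical registration target.
#'
#' @param subdivisions icosphere subdivision count (see [make_icosphere()]).
#' @param amplitude relative bump amplitude, in `[0, 1)`. Values `>= 1` are
#'   rejected (radial displacement would risk self-intersection).
#' @param harmonic_order highest spherical-harmonic degree of the deformation.
#' @param radius sphere radius in mm.
#' @param seed integer seed for the random harmonic coefficients.
#' @return a `surface_pair`.
#' @examples
#' p <- make_bumpy_pair(2, amplitude = 0.25, harmonic_order = 4, seed = 1)
#' p
#' @export
make_bumpy_pair <- function(subdivisions, amplitude = 0.25, harmonic_order = 4,
                            radius = 100, seed = 1) {
  assert_scalar_number(amplitude, "amplitude", lower = 0)
  if (amplitude >= 1) {
    stop("`amplitude` must be < 1 (self-intersection risk)", call. = FALSE)
  }
  assert_scalar_number(harmonic_order, "harmonic_order", lower = 1)
  sphere <- make_icosphere(subdivisions, radius = radius)
  dirs <- sphere$coordinates / radius
  if (amplitude == 0) {
    return(surface_pair(sphere, sphere, radius = radius))
  }
  B <- real_sph_harm_basis(dirs, as.integer(harmonic_order))
  coef <- with_seed(seed, stats::rnorm(ncol(B)))
  f <- drop(B %*% coef)
  f <- f - mean(f)
  f <- f / max(abs(f))
  surf <- surface_mesh(dirs * radius * (1 + amplitude * f), sphere$triangles,
                       check_connected = FALSE)
  surface_pair(surf, sphere, radius = radius)
}

new_distance_matrix <- function(values, metric_kind) {
  structure(list(values = values, metric_kind = metric_kind),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d x %d, metric: %s\n",
              nrow(x$values), ncol(x$values), x$metric_kind))
  invisible(x)
}

#' Pairwise Euclidean distances between mesh vertices
#'
#' @param mesh a `surface_mesh`, or a numeric coordinate matrix.
#' @param max_vertices size guard for the dense result (default 20000).
#' @return a `distance_matrix` with `metric_kind = "euclidean"`: a symmetric
#'   vertex-by-vertex matrix of straight-line mm distances, zero diagonal.
#' @export
pairwise_euclidean <- function(mesh, max_vertices = 20000L) {
  coords <- if (inherits(mesh, "surface_mesh")) mesh$coordinates else as.matrix(mesh)
  n <- nrow(coords)
  if (n > max_vertices) {
    stop("dense distance matrix would have ", n, " > ", max_vertices,
         " rows; raise `max_vertices` to override", call. = FALSE)
  }
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- NULL
  # dist() can leave tiny asymmetries after as.matrix on some BLAS; enforce
  d <- (d + t(d)) / 2
  diag(d) <- 0
  new_distance_matrix(d, "euclidean")
}

#' Pairwise geodesic distances over the mesh edge graph
#'
#' Shortest-path distance where each triangulation edge is weighted by its
#' Euclidean length (Dijkstra). This edge-graph geodesic slightly overshoots
#' the exact polyhedral geodesic but is deterministic and exact for paths
#' along edges.
#'
#' @param mesh a connected `surface_mesh`.
#' @param max_vertices size guard for the dense result.
#' @return a `distance_matrix` with `metric_kind = "geodesic"`.
#' @export
pairwise_geodesic <- function(mesh, max_vertices = 20000L) {
  stopifnot(inherits(mesh, "surface_mesh"))
  n <- n_vertices(mesh)
  if (n > max_vertices) {
    stop("dense distance matrix would have ", n, " > ", max_vertices,
         " rows; raise `max_vertices` to override", call. = FALSE)
  }
  comp <- mesh_components(mesh)
  if (comp$no > 1L) {
    stop("mesh is disconnected (component sizes: ",
         paste(comp$csize, collapse = ", "), ")", call. = FALSE)
  }
  g <- mesh_graph(mesh)
  d <- igraph::distances(g, algorithm = "dijkstra")
  dimnames(d) <- NULL
  d <- (d + t(d)) / 2
  diag(d) <- 0
  new_distance_matrix(d, "geodesic")
}
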