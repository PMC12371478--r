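# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `expr`,
#' and restores the previous RNG state so that library calls never perturb a
#' user's random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a vector of child seeds from one master seed. Children are drawn
# from a seeded stream so that substreams for different units of work
# (maps, thresholds, ...) are decoupled from one another and from the order
# in which they are consumed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# Cheap deterministic fingerprint of a mesh: vertex/triangle counts plus a
# few rounded coordinate moments. Used for provenance, not cryptography.
mesh_fingerprint <- function(mesh) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$coordinates
  paste0(
    "v", nrow(v), "t", nrow(mesh$triangles), "s",
    format(round(sum(v), 6), scientific = FALSE, trim = TRUE), "q",
    format(round(sum(v^2), 4), scientific = FALSE, trim = TRUE)
  )
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
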