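# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards so seeded package calls never perturb the
# user's stream. A NULL seed runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derived from a master seed; keeps results < 2^31
# and decorrelated across stages/steps.
derive_seed <- function(seed, salt) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(salt)) %% 2147483629L)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Symmetric, zero-diagonal, nonnegative check applied to every distance
# matrix the package emits.
check_distance_matrix <- function(m, what = "distance matrix") {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-10, check.attributes = FALSE)))
    stopf("%s is not symmetric", what)
  if (any(abs(diag(m)) > 1e-12)) stopf("%s has a nonzero diagonal", what)
  if (any(m < -1e-12, na.rm = TRUE)) stopf("%s has negative entries", what)
  invisible(m)
}

new_dist_matrix <- function(values, labels, dist_type) {
  dimnames(values) <- list(labels, labels)
  check_distance_matrix(values, dist_type)
  structure(values, dist_type = dist_type, class = c("dendro_dist", "matrix", "array"))
}

#' @export
print.dendro_dist <- function(x, ...) {
  cat(sprintf("Site distance matrix (%s): %d sites\n", attr(x, "dist_type"), nrow(x)))
  cat(sprintf("  range %.4g - %.4g\n", min(x[upper.tri(x)], na.rm = TRUE),
              max(x[upper.tri(x)], na.rm = TRUE)))
  invisible(x)
}
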