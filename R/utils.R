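# Internal helpers: seeded RNG scoping, seed derivation, matrix coercion.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the random number generator seeded to `seed`, then
#' restores the caller's RNG state, so seeded internals (e.g. the bootstrap)
#' never perturb user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

#' Derive a per-system RNG seed from a master seed and a system label
#'
#' Hashes the label (Horner scheme over its UTF-8 code points, modulo the
#' Mersenne-like prime 2147483629) and folds the master seed in, so that
#' per-system bootstrap streams do not depend on the order in which systems
#' are processed.
#'
#' @param master integer master seed.
#' @param id character label (e.g. a system id).
#' @return An integer seed in `[0, 2147483628]`.
#' @export
#' @examples
#' derive_seed(42, "Megapharanaspis")
derive_seed <- function(master, id) {
  stopifnot(length(master) == 1L, is.finite(master), length(id) == 1L)
  p <- 2147483629
  h <- 0
  for (k in utf8ToInt(as.character(id))) h <- (h * 31 + k) %% p
  as.integer((h + (as.numeric(master) %% p)) %% p)
}

# Coerce to a numeric point matrix (rows = parts, cols = axes).
as_point_matrix <- function(points, arg = "points") {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(dim(points))) points <- matrix(points, ncol = 1L)
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) {
    stop("`", arg, "` must contain only finite values", call. = FALSE)
  }
  points
}

# Number of decimal digits of a positive integer (run-length count cost).
n_digits <- function(k) nchar(as.character(as.integer(k)))
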