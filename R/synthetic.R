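# Seeded synthetic generators: analytic configurations with known index
# values (simplex, lattice, Gaussian clouds), trilobite-like segment tables
# and ant-colony-like head outlines. Every generator is a pure function of
# its parameters and seed, so all fixtures are built in code at test time.

#' Vertices of a regular simplex
#'
#' n mutually equidistant points embedded in n-1 dimensions: the analytic
#' perfect-regularity configuration (all pairwise distances equal `edge`).
#' Construction: the n standard basis vectors of R^n, projected onto the
#' (n-1)-dimensional affine span of their centroid and rescaled.
#'
#' @param n number of vertices (>= 2).
#' @param edge common pairwise distance (default 1).
#' @return `n x (n-1)` matrix.
#' @export
#' @examples
#' d <- dist(simplex_points(4))  # six equal distances: regular tetrahedron
simplex_points <- function(n, edge = 1) {
  if (n < 2) stop("a simplex needs n >= 2 vertices", call. = FALSE)
  if (edge <= 0) stop("`edge` must be positive", call. = FALSE)
  x <- diag(n)
  xc <- sweep(x, 2, colMeans(x))
  basis <- svd(xc, nu = 0, nv = n - 1L)$v        # orthonormal span basis
  pts <- (xc %*% basis) * (edge / sqrt(2))       # basis-vector gap is sqrt(2)
  colnames(pts) <- paste0("axis", seq_len(ncol(pts)))
  pts
}

#' Regular rectangular lattice in the plane
#'
#' On a square lattice the 1st- and 2nd-order nearest-neighbour distances
#' are all identical (pooled NND CV = 0) while the full set of pairwise
#' distances is not (pairwise CV > 0) -- the configuration that motivates
#' the dimensionality-aware regularity dispatch.
#'
#' @param rows,cols lattice dimensions (>= 2 each).
#' @param spacing grid spacing (default 1).
#' @return `rows*cols x 2` matrix.
#' @export
square_lattice <- function(rows, cols, spacing = 1) {
  if (rows < 2 || cols < 2) stop("lattice needs rows, cols >= 2",
                                 call. = FALSE)
  g <- expand.grid(x = (seq_len(cols) - 1) * spacing,
                   y = (seq_len(rows) - 1) * spacing)
  as.matrix(g)
}

#' Isotropic Gaussian point cloud
#'
#' i.i.d. normal coordinates with standard deviation `sigma`; the expected
#' sum of (sample) variances is `n_axes * sigma^2`.
#'
#' @param n number of points.
#' @param n_axes dimensionality.
#' @param sigma coordinate standard deviation.
#' @param seed integer seed.
#' @return `n x n_axes` matrix.
#' @export
gaussian_system <- function(n, n_axes, sigma, seed) {
  stopifnot(n >= 1, n_axes >= 1, sigma >= 0)
  with_seed(seed, matrix(rnorm(n * n_axes, sd = sigma), nrow = n))
}

#' Synthetic segmented body (trilobite-like part table)
#'
#' Emulates a two-variable thoracic-segment table: segments sit at positions
#' t in `[0, 1]` along the anteroposterior axis and carry two lobe widths
#' (`axial` widening, `pleural` tapering) that follow a smooth gradient --
#' a constant-speed circular arc in the two variables, so equal position
#' steps are equal morphospace steps -- whose total span scales with
#' `differentiation`. Positions are a convex mixture, with weight
#' `irregularity`, of perfectly equal spacing and uniform-random placement
#' (sorted uniform draws, so segments keep their anteroposterior order):
#' at 0 the gradient is sampled perfectly evenly, at 1 positions are the
#' order statistics of a uniform sample.
#'
#' @param n_segments number of segments (>= 1).
#' @param differentiation gradient span (`[0, 2]` sensible; 0 gives
#'   identical segments).
#' @param irregularity mixture weight in `[0, 1]`.
#' @param seed integer seed.
#' @param system_id system label (default `"body"`).
#' @return A [part_table] with variables `axial` and `pleural` and
#'   `position_rank` metadata.
#' @export
synthetic_body <- function(n_segments, differentiation, irregularity, seed,
                           system_id = "body") {
  stopifnot(n_segments >= 1, differentiation >= 0,
            irregularity >= 0, irregularity <= 1)
  t_even <- if (n_segments == 1L) 0.5 else
    seq(0, 1, length.out = n_segments)
  t_rand <- with_seed(seed, sort(runif(n_segments)))
  t <- (1 - irregularity) * t_even + irregularity * t_rand
  d <- differentiation
  phi <- (2 * pi / 3) * (t - 0.5)              # 120 degrees of arc
  axial <- 1 + 0.45 * d * sin(phi)             # widening along the body
  pleural <- 1 + 0.45 * d * (cos(phi) - 0.8)   # anterior taper
  part_table(data.frame(
    system_id = system_id,
    part_id = sprintf("seg%02d", seq_len(n_segments)),
    position_rank = seq_len(n_segments),
    axial = axial, pleural = pleural,
    stringsAsFactors = FALSE))
}

# Per-caste superellipse offsets: (aspect-ratio delta, exponent delta).
# Arbitrary but fixed: any smooth, closed, one-parameter-separable family
# of head-like outlines would do.
.caste_offsets <- list(
  male       = c(-0.25, 0.0),
  queen      = c(0.25, 0.6),
  worker     = c(0.0, -0.3),
  minor      = c(-0.10, -0.4),
  major      = c(0.15, 0.3),
  supermajor = c(0.35, 0.9))

.caste_sets <- list(
  monomorphic = c("male", "queen", "worker"),
  dimorphic   = c("male", "queen", "minor", "major"),
  trimorphic  = c("male", "queen", "minor", "major", "supermajor"))

#' Synthetic ant colony (superellipse head outlines per polyphenism)
#'
#' One closed head outline per polyphenism: males, queens, and one, two or
#' three worker polymorphisms for monomorphic, dimorphic and trimorphic
#' caste structures (3, 4 and 5 parts). Heads are superellipses
#' `|x/a|^m + |y/b|^m = 1` whose aspect ratio and exponent are offset per
#' caste, scaled by `shape_sep`; a small seeded jitter (SD
#' `0.02 * shape_sep`) individualises specimens. At `shape_sep = 0` all
#' outlines are identical.
#'
#' @param caste_structure `"monomorphic"`, `"dimorphic"` or `"trimorphic"`.
#' @param shape_sep caste shape-separation scale (>= 0, default 1).
#' @param seed integer seed.
#' @param n_points vertices per outline (default 240).
#' @return Named list of [outline] objects (names = polyphenism labels).
#' @export
synthetic_colony <- function(caste_structure = c("monomorphic", "dimorphic",
                                                 "trimorphic"),
                             shape_sep = 1, seed, n_points = 240) {
  caste_structure <- match.arg(caste_structure)
  stopifnot(shape_sep >= 0)
  castes <- .caste_sets[[caste_structure]]
  jit <- with_seed(seed,
                   matrix(rnorm(2 * length(castes), sd = 0.02 * shape_sep),
                          ncol = 2))
  u <- 2 * pi * (seq_len(n_points) - 1) / n_points
  out <- lapply(seq_along(castes), function(i) {
    off <- .caste_offsets[[castes[i]]]
    aspect <- 1 + shape_sep * off[1] + jit[i, 1]
    m <- 2 + shape_sep * off[2] + jit[i, 2]
    if (m <= 0.2) m <- 0.2                     # keep the curve closed/sane
    x <- sign(cos(u)) * abs(cos(u))^(2 / m)
    y <- aspect * sign(sin(u)) * abs(sin(u))^(2 / m)
    outline(cbind(x = x, y = y), source_id = castes[i])
  })
  names(out) <- castes
  out
}
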