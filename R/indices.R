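# The three complexity-space coordinates of a system: part number, degree of
# part differentiation (sum of variances, bootstrapped), and (ir)regularity
# of differentiation (coefficient of variation of inter-part distances).
# Sample statistics use the n-1 denominator throughout.

#' Number of parts of a system
#'
#' Counts the morphospace rows belonging to `system_id`. Coincident
#' (superimposed) parts count separately.
#'
#' @param space a [morphospace].
#' @param system_id system label.
#' @return Integer count.
#' @export
part_count <- function(space, system_id) {
  stopifnot(inherits(space, "morphospace"))
  hits <- space$system_of == system_id
  if (!any(hits)) stop("unknown system: ", system_id, call. = FALSE)
  sum(hits)
}

#' Sum of univariate variances (differentiation index)
#'
#' Sums the sample variance of each morphospace axis over a set of points.
#' Rotation- and translation-invariant (rigid motions do not change it);
#' uniform scaling by `c` multiplies it by `c^2`. A single point has, by
#' convention, a sum of variances of 0 (degenerate: nothing to differentiate).
#'
#' @param points numeric matrix (rows = parts) or anything coercible.
#' @return Non-negative scalar.
#' @export
#' @examples
#' sum_of_variances(rbind(c(0, 0), c(2, 0)))  # 2
sum_of_variances <- function(points) {
  pts <- as_point_matrix(points)
  if (nrow(pts) < 1L) stop("no points", call. = FALSE)
  if (nrow(pts) == 1L) return(0)
  sum(apply(pts, 2, var))
}

#' Sum of per-axis ranges (optional spread index)
#'
#' Offered as a variant only: unlike the sum of variances it depends on the
#' orientation of the reference axes and is more sensitive to sample size,
#' so it never enters the default complexity profile.
#'
#' @inheritParams sum_of_variances
#' @return Non-negative scalar.
#' @export
sum_of_ranges <- function(points) {
  pts <- as_point_matrix(points)
  sum(apply(pts, 2, function(x) diff(range(x))))
}

#' Mean pairwise distance (optional spread index)
#'
#' @inheritParams sum_of_variances
#' @return Non-negative scalar; 0 for a single point.
#' @export
mean_pairwise_distance <- function(points) {
  pts <- as_point_matrix(points)
  if (nrow(pts) < 2L) return(0)
  mean(dist(pts))
}

#' Bootstrapped sum of variances
#'
#' Each pseudoreplicate resamples the system's parts with replacement to the
#' original sample size and recomputes the sum of variances; the median over
#' replicates is the differentiation score. Fully reproducible given `seed`,
#' and the caller's RNG state is left untouched.
#'
#' @inheritParams sum_of_variances
#' @param reps number of pseudoreplicates (default 100).
#' @param seed integer seed (required).
#' @return List with elements `median`, `replicates`, `reps`, `seed`.
#' @export
bootstrap_sov <- function(points, reps = 100, seed) {
  pts <- as_point_matrix(points)
  if (reps < 1) stop("`reps` must be >= 1", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  n <- nrow(pts)
  vals <- with_seed(seed, vapply(seq_len(reps), function(r) {
    idx <- sample.int(n, n, replace = TRUE)
    sum_of_variances(pts[idx, , drop = FALSE])
  }, numeric(1)))
  list(median = median(vals), replicates = vals,
       reps = as.integer(reps), seed = as.integer(seed))
}

#' Coefficient of variation of all pairwise distances
#'
#' Regularity index for systems whose parts *can* all be mutually
#' equidistant (few parts relative to the number of axes): sample standard
#' deviation of the n(n-1)/2 Euclidean inter-part distances divided by their
#' mean. 0 means perfect regularity (a regular simplex); larger values mean
#' a more irregular, harder-to-describe arrangement. Invariant to rigid
#' motion and to uniform scaling.
#'
#' With exactly two parts there is a single distance, which exhibits no
#' variation: the CV is defined as 0 and flagged `degenerate`. If all parts
#' coincide the mean distance is 0 and the CV is undefined (`NA`,
#' `undefined` attribute), never reported as 0.
#'
#' @inheritParams sum_of_variances
#' @return Scalar (possibly `NA` with attribute `undefined = TRUE`;
#'   the 2-part case carries attribute `degenerate = TRUE`).
#' @export
#' @examples
#' pairwise_distance_cv(simplex_points(3))        # 0
#' pairwise_distance_cv(cbind(c(0, 1, 3), 0))     # 0.5
pairwise_distance_cv <- function(points) {
  pts <- as_point_matrix(points)
  if (nrow(pts) < 2L) {
    return(structure(NA_real_, undefined = TRUE))
  }
  d <- as.numeric(dist(pts))
  if (length(d) == 1L) {
    return(structure(0, degenerate = TRUE))
  }
  m <- mean(d)
  if (m == 0) return(structure(NA_real_, undefined = TRUE))
  sd(d) / m
}

#' Coefficient of variation of pooled low-order nearest-neighbour distances
#'
#' Regularity index for systems with more parts than the dimensionality
#' allows to be mutually equidistant. For every part, its distances to its
#' 1st- and 2nd-nearest neighbours (by sorted distance; ties share ranks in
#' sorted order) are pooled across parts, and the sample-SD/mean ratio of
#' the pooled multiset is returned. On a regular square lattice these
#' low-order distances are all identical, giving 0, even though the CV of
#' *all* pairwise distances on the same lattice is positive.
#'
#' @inheritParams sum_of_variances
#' @param orders neighbour orders to pool (default `c(1, 2)`).
#' @return Scalar (`NA` + `undefined` attribute if all parts coincide).
#' @export
nnd_cv <- function(points, orders = c(1, 2)) {
  pts <- as_point_matrix(points)
  n <- nrow(pts)
  if (n < max(orders) + 1L) {
    stop("need at least ", max(orders) + 1L,
         " points for order-", max(orders), " neighbours", call. = FALSE)
  }
  dm <- as.matrix(dist(pts))
  pooled <- unlist(lapply(seq_len(n), function(i) {
    sort(dm[i, -i])[orders]
  }), use.names = FALSE)
  m <- mean(pooled)
  if (m == 0) return(structure(NA_real_, undefined = TRUE))
  sd(pooled) / m
}

#' Regularity index with dimensionality-aware dispatch
#'
#' Mutual equidistance of n points is geometrically possible only in
#' n-1 or more dimensions. Accordingly: if `n_axes >= n_parts - 1`, the CV
#' of all pairwise distances is used (`all_pairwise`); otherwise the CV of
#' pooled 1st/2nd-order nearest-neighbour distances (`nnd_1_2`).
#'
#' @inheritParams sum_of_variances
#' @param n_axes dimensionality of the morphospace the points live in
#'   (default: their column count).
#' @return List with `value` (scalar, `NA` if undefined) and `method`
#'   (`"all_pairwise"` or `"nnd_1_2"`).
#' @export
regularity_index <- function(points, n_axes = NULL) {
  pts <- as_point_matrix(points)
  if (is.null(n_axes)) n_axes <- ncol(pts)
  n <- nrow(pts)
  if (n < 2L) stop("regularity needs at least 2 points", call. = FALSE)
  if (n_axes >= n - 1L) {
    list(value = pairwise_distance_cv(pts), method = "all_pairwise")
  } else {
    list(value = nnd_cv(pts), method = "nnd_1_2")
  }
}

#' Complexity profile of one system
#'
#' Assembles the system's coordinates on the three complexity axes: part
#' count, sum of variances (raw and bootstrap median), and regularity CV
#' under the dimensionality dispatch rule. Undefined regularity (a single
#' part, or fully coincident parts) is recorded as `NA`, never as 0. The
#' bootstrap stream is derived from `seed` and the system label, so results
#' do not depend on the order systems are processed in.
#'
#' @param space a [morphospace].
#' @param system_id system label.
#' @param reps bootstrap pseudoreplicates (default 100).
#' @param seed master integer seed.
#' @return One-row data.frame of class `complexity_profile` with columns
#'   `system_id`, `n_parts`, `sov`, `sov_boot_median`, `regularity_cv`,
#'   `regularity_method`, `boot_reps`, `seed`.
#' @export
complexity_profile <- function(space, system_id, reps = 100, seed) {
  stopifnot(inherits(space, "morphospace"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  rows <- which(space$system_of == system_id)
  if (!length(rows)) stop("unknown system: ", system_id, call. = FALSE)
  pts <- space$points[rows, , drop = FALSE]
  n <- length(rows)
  sov <- sum_of_variances(pts)
  boot <- bootstrap_sov(pts, reps = reps, seed = derive_seed(seed, system_id))
  if (n >= 2L) {
    reg <- regularity_index(pts, n_axes = ncol(space$points))
    reg_cv <- as.numeric(reg$value)
    reg_method <- reg$method
  } else {
    reg_cv <- NA_real_
    reg_method <- NA_character_
  }
  out <- data.frame(
    system_id = system_id, n_parts = n, sov = sov,
    sov_boot_median = boot$median, regularity_cv = reg_cv,
    regularity_method = reg_method, boot_reps = as.integer(reps),
    seed = as.integer(seed), stringsAsFactors = FALSE)
  class(out) <- c("complexity_profile", "data.frame")
  out
}

#' Complexity space of all systems in a morphospace
#'
#' One [complexity_profile] row per system, computed in the pooled
#' morphospace coordinates and ordered by system label.
#'
#' @inheritParams complexity_profile
#' @return data.frame of class `complexity_space`, one row per system.
#' @export
build_complexity_space <- function(space, reps = 100, seed) {
  stopifnot(inherits(space, "morphospace"))
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  ids <- systems(space)
  if (!length(ids)) stop("empty morphospace", call. = FALSE)
  rows <- lapply(ids, function(id)
    complexity_profile(space, id, reps = reps, seed = seed))
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  class(out) <- c("complexity_space", "data.frame")
  out
}

#' @export
print.complexity_space <- function(x, ...) {
  meta <- if (!is.null(x$boot_reps) && !is.null(x$seed)) {
    paste0("; boot_reps = ", x$boot_reps[1], ", seed = ", x$seed[1])
  } else ""
  cat("<complexity_space> ", nrow(x), " system(s)", meta, "\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}
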