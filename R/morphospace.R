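# Morphospace: parts embedded as points in a shared k-axis space. All systems
# share one space -- the unit of observation is the part, not the species --
# so normalization and ordination are always pooled.

#' Construct a morphospace
#'
#' @param points numeric matrix, one row per part, one column per axis.
#' @param system_of character vector mapping each row to its system.
#' @param part_of optional character vector of part identifiers.
#' @param axis_meta data.frame with columns `label`, `provenance`
#'   (`raw`/`normalized`/`efa`/`PC`) and `var_fraction` (NA unless PC axes).
#' @return An object of class `morphospace`.
#' @export
morphospace <- function(points, system_of, part_of = NULL, axis_meta = NULL) {
  points <- as_point_matrix(points)
  if (nrow(points) < 1L) stop("a morphospace needs at least one part",
                              call. = FALSE)
  system_of <- as.character(system_of)
  if (length(system_of) != nrow(points)) {
    stop("`system_of` must map every row of `points`", call. = FALSE)
  }
  if (is.null(part_of)) part_of <- as.character(seq_len(nrow(points)))
  if (is.null(axis_meta)) {
    axis_meta <- data.frame(
      label = if (is.null(colnames(points)))
        paste0("axis", seq_len(ncol(points))) else colnames(points),
      provenance = "raw", var_fraction = NA_real_,
      stringsAsFactors = FALSE)
  }
  stopifnot(nrow(axis_meta) == ncol(points))
  if (identical(axis_meta$provenance[1], "PC")) {
    s <- sum(axis_meta$var_fraction)
    if (abs(s - 1) > 1e-9) {
      stop("PC variance fractions must sum to 1 (got ", format(s), ")",
           call. = FALSE)
    }
  }
  colnames(points) <- axis_meta$label
  structure(list(points = points, system_of = system_of, part_of = part_of,
                 axis_meta = axis_meta),
            class = "morphospace")
}

#' @export
print.morphospace <- function(x, ...) {
  cat("<morphospace> ", nrow(x$points), " parts x ", ncol(x$points),
      " axes (", paste(unique(x$axis_meta$provenance), collapse = "/"),
      "), ", length(unique(x$system_of)), " system(s)\n", sep = "")
  invisible(x)
}

#' @rdname morphospace
#' @param x a `morphospace`.
#' @export
n_parts_total <- function(x) nrow(x$points)

#' @rdname morphospace
#' @export
systems <- function(x) sort(unique(x$system_of))

#' Build a morphospace from a part table
#'
#' One point per part; axis order follows `variables`; the table's
#' normalization provenance is carried onto the axes. Coincident parts
#' (identical rows) are legal and retained: superimposed segments still count
#' as distinct parts.
#'
#' @param table a [part_table].
#' @param variables variables to use as axes (default: all).
#' @return A [morphospace].
#' @export
build_morphospace <- function(table, variables = part_variables(table)) {
  stopifnot(inherits(table, "part_table"))
  unknown <- setdiff(variables, names(table))
  if (length(unknown)) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pts <- as.matrix(as.data.frame(table)[, variables, drop = FALSE])
  morphospace(
    pts, system_of = table$system_id, part_of = table$part_id,
    axis_meta = data.frame(label = variables,
                           provenance = attr(table, "provenance"),
                           var_fraction = NA_real_,
                           stringsAsFactors = FALSE))
}

#' Principal component ordination of a morphospace
#'
#' Rotates the pooled point cloud (all parts of all systems together) onto
#' its principal component axes. Centering is on by default; unit-scaling is
#' off by default because normalized measurements and Fourier coefficients
#' are already commensurate. The rotation is an isometry of the centered
#' cloud, so the sum of per-axis variances -- the differentiation index --
#' is unchanged.
#'
#' @param space a [morphospace] with at least 2 parts.
#' @param center,scale. passed to [stats::prcomp].
#' @return A [morphospace] on PC axes; `axis_meta$var_fraction` holds each
#'   axis's fraction of total variance (non-increasing, summing to 1).
#' @export
pca_ordinate <- function(space, center = TRUE, scale. = FALSE) {
  stopifnot(inherits(space, "morphospace"))
  if (nrow(space$points) < 2L) {
    stop("PCA needs at least 2 parts", call. = FALSE)
  }
  tot <- sum(apply(space$points, 2, var))
  if (tot == 0) {
    stop("all parts coincide: no variance to ordinate", call. = FALSE)
  }
  p <- prcomp(space$points, center = center, scale. = scale.)
  varf <- p$sdev^2 / sum(p$sdev^2)
  morphospace(
    p$x, system_of = space$system_of, part_of = space$part_of,
    axis_meta = data.frame(label = colnames(p$x), provenance = "PC",
                           var_fraction = varf, stringsAsFactors = FALSE))
}

#' Restrict a morphospace to a subset of axes
#'
#' Mainly for reproducing analyses that keep only the first few PCs.
#' Variance fractions of retained PC axes are kept as fractions of the
#' *original* total variance, and flagged by renormalizing is deliberately
#' not done, so the subset is honest about discarded variance.
#'
#' @param space a [morphospace].
#' @param axes integer indices (or labels) of axes to keep.
#' @return A [morphospace].
#' @export
subset_axes <- function(space, axes) {
  stopifnot(inherits(space, "morphospace"))
  if (is.character(axes)) axes <- match(axes, space$axis_meta$label)
  if (anyNA(axes) || any(axes < 1 | axes > ncol(space$points))) {
    stop("unknown axis selection", call. = FALSE)
  }
  out <- space
  out$points <- space$points[, axes, drop = FALSE]
  out$axis_meta <- space$axis_meta[axes, , drop = FALSE]
  class(out) <- "morphospace"
  out
}
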