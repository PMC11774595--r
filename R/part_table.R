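# PartTable: long-format table of parts x continuous variables, with system
# labels. The raw-measurement entry point of the toolkit (one row per serial
# homologue: a thoracic segment, a worker caste, ...).

#' Construct a validated part table
#'
#' A part table holds one row per part with its parent system, an identifier
#' unique within that system, optional `position_rank` metadata, and one or
#' more continuous measurement variables.
#'
#' @param x data.frame with columns `system_id`, `part_id`, optionally
#'   `position_rank`, plus numeric measurement columns.
#' @param variables character vector naming the measurement columns. Default:
#'   every numeric column that is not `position_rank`.
#' @param provenance provenance flag attached to the variables
#'   (`"raw"`, `"normalized"` or `"efa"`).
#' @return The data.frame with class `part_table` and attributes
#'   `variables` and `provenance`.
#' @export
#' @examples
#' pt <- part_table(data.frame(
#'   system_id = "tri1", part_id = c("s1", "s2"),
#'   axial = c(2, 4), pleural = c(1, 1)))
#' part_variables(pt)
part_table <- function(x, variables = NULL, provenance = "raw") {
  if (!is.data.frame(x)) stop("`x` must be a data.frame", call. = FALSE)
  need <- c("system_id", "part_id")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x$system_id <- as.character(x$system_id)
  x$part_id <- as.character(x$part_id)
  if (nrow(x) < 1L) stop("part table has no rows", call. = FALSE)
  if (is.null(variables)) {
    num <- vapply(x, is.numeric, logical(1))
    variables <- setdiff(names(x)[num], c("position_rank"))
  }
  if (length(variables) < 1L) {
    stop("a part table needs at least one measurement variable", call. = FALSE)
  }
  unknown <- setdiff(variables, names(x))
  if (length(unknown)) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (v in variables) {
    if (!is.numeric(x[[v]])) {
      stop("variable '", v, "' is not numeric", call. = FALSE)
    }
    bad <- which(!is.finite(x[[v]]))
    if (length(bad)) {
      stop("variable '", v, "' has non-finite values in row(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  dup <- duplicated(paste(x$system_id, x$part_id, sep = "\r"))
  if (any(dup)) {
    stop("duplicate (system_id, part_id) in row(s) ",
         paste(which(dup), collapse = ", "), call. = FALSE)
  }
  provenance <- match.arg(provenance, c("raw", "normalized", "efa"))
  structure(x, class = c("part_table", "data.frame"),
            variables = variables, provenance = provenance)
}

#' @rdname part_table
#' @export
part_variables <- function(x) attr(x, "variables")

#' @export
print.part_table <- function(x, ...) {
  cat("<part_table> ", nrow(x), " parts, ",
      length(unique(x$system_id)), " system(s), variables: ",
      paste(part_variables(x), collapse = ", "),
      " [", attr(x, "provenance"), "]\n", sep = "")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Normalize measurements by their per-system, per-variable mean
#'
#' Size control for measurement morphospaces: each value is divided by the
#' mean of that variable within its own system, so every system's per-variable
#' mean becomes exactly 1 and systems of very different absolute size become
#' comparable. The operation is idempotent and invariant to uniform rescaling
#' of a system's raw measurements.
#'
#' @param table a [part_table].
#' @param variables variables to normalize (default: all measurement
#'   variables of `table`).
#' @return A [part_table] with provenance `"normalized"`.
#' @export
#' @examples
#' pt <- part_table(data.frame(system_id = "t", part_id = c("a", "b"),
#'                             axial = c(2, 4)))
#' normalize_by_system_mean(pt)$axial  # 2/3, 4/3
normalize_by_system_mean <- function(table, variables = part_variables(table)) {
  stopifnot(inherits(table, "part_table"))
  unknown <- setdiff(variables, part_variables(table))
  if (length(unknown)) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- table
  for (v in variables) {
    means <- tapply(out[[v]], out$system_id, mean)
    bad <- names(means)[!is.finite(means) | means == 0]
    if (length(bad)) {
      stop("cannot normalize variable '", v, "': zero or non-finite mean in ",
           "system(s) ", paste(bad, collapse = ", "), call. = FALSE)
    }
    out[[v]] <- out[[v]] / as.numeric(means[out$system_id])
  }
  attr(out, "provenance") <- "normalized"
  out
}
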