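# Readers and writers: part-table CSV, mask manifests (PNG/TIFF), the
# complexity-space CSV, and the 3D complexity-space plot. CSV is RFC-4180
# with a header; undefined regularity is written as an empty cell, never 0.

#' Read a part table from CSV
#'
#' Expects a header with `system_id`, `part_id`, then measurement columns.
#' Non-numeric measurement cells and duplicate `(system_id, part_id)` keys
#' are rejected with row numbers. Extra non-numeric columns are carried
#' through as metadata.
#'
#' @param path CSV file path.
#' @param variables measurement columns (default: every numeric column
#'   except `position_rank`).
#' @return A [part_table].
#' @export
read_part_table <- function(path, variables = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("system_id", "part_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(variables)) {
    variables <- setdiff(names(df), c("system_id", "part_id",
                                      "position_rank"))
    variables <- variables[vapply(df[variables], function(col)
      is.numeric(col) || all(grepl("^\\s*-?[0-9.eE+]+\\s*$", col) |
                               is.na(col)), logical(1))]
  }
  for (v in variables) {
    vals <- suppressWarnings(as.numeric(df[[v]]))
    bad <- which(is.na(vals) | !is.finite(vals))
    if (length(bad)) {
      stop("non-numeric or missing value for variable '", v,
           "' in data row(s) ", paste(bad, collapse = ", "), " of ", path,
           call. = FALSE)
    }
    df[[v]] <- vals
  }
  part_table(df, variables = variables)
}

#' Write a part table to CSV
#'
#' @param table a [part_table].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_part_table <- function(table, path) {
  stopifnot(inherits(table, "part_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Read one single-channel image as a numeric matrix (rows = image rows).
read_mask_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format '.", ext, "' for ", path, call. = FALSE))
  if (length(dim(img)) == 3L) img <- img[, , 1]   # first channel
  img
}

#' Read a directory of binary masks via a manifest
#'
#' The manifest CSV maps `filename` to `system_id` and `part_id`. Masks are
#' binarized at `value > 0` (so 0/255 grayscale works unchanged).
#'
#' @param dir directory containing the mask images.
#' @param manifest path to the manifest CSV
#'   (columns `filename`, `system_id`, `part_id`).
#' @return List of records, each with `mask` (logical matrix), `system_id`,
#'   `part_id`.
#' @export
read_masks <- function(dir, manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest,
                                   call. = FALSE)
  mf <- read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("filename", "system_id", "part_id")
  miss <- setdiff(need, names(mf))
  if (length(miss)) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(mf)) stop("manifest is empty", call. = FALSE)
  lapply(seq_len(nrow(mf)), function(i) {
    f <- file.path(dir, mf$filename[i])
    if (!file.exists(f)) stop("mask file not found: ", f, call. = FALSE)
    list(mask = read_mask_file(f) > 0,
         system_id = as.character(mf$system_id[i]),
         part_id = as.character(mf$part_id[i]))
  })
}

#' Write a complexity space to CSV
#'
#' Columns: `system_id`, `n_parts`, `sov`, `sov_boot_median`,
#' `regularity_cv`, `regularity_method`, `boot_reps`, `seed`. Undefined
#' regularity is written as an empty cell.
#'
#' @param cs a `complexity_space` (see [build_complexity_space]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_complexity_space <- function(cs, path) {
  stopifnot(inherits(cs, "complexity_space") ||
              inherits(cs, "complexity_profile"))
  cols <- c("system_id", "n_parts", "sov", "sov_boot_median",
            "regularity_cv", "regularity_method", "boot_reps", "seed")
  df <- as.data.frame(cs)[, cols]
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a complexity space back from CSV
#'
#' @param path CSV written by [write_complexity_space].
#' @return data.frame of class `complexity_space`.
#' @export
read_complexity_space <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$regularity_method <- as.character(df$regularity_method)
  class(df) <- c("complexity_space", "data.frame")
  df
}

#' 3D scatter of a complexity space
#'
#' Plots systems on the three complexity axes (part number, bootstrapped
#' differentiation, regularity CV), optionally coloured by a continuous
#' covariate column (e.g. first-occurrence age or colony size). Systems
#' with undefined regularity cannot be placed and are dropped with a
#' warning.
#'
#' @param cs a `complexity_space`, possibly augmented with covariate
#'   columns (left-join on `system_id` upstream).
#' @param color_by optional name of a numeric column of `cs`.
#' @param path output image path (`.png`).
#' @param width,height device size in pixels.
#' @return `path`, invisibly.
#' @export
plot_complexity_space <- function(cs, color_by = NULL, path,
                                  width = 800, height = 700) {
  stopifnot(inherits(cs, "complexity_space"))
  df <- as.data.frame(cs)
  drop <- is.na(df$regularity_cv)
  if (any(drop)) {
    warning("omitting ", sum(drop),
            " system(s) with undefined regularity: ",
            paste(df$system_id[drop], collapse = ", "), call. = FALSE)
    df <- df[!drop, , drop = FALSE]
  }
  if (!nrow(df)) stop("nothing to plot", call. = FALSE)
  cols <- "black"
  if (!is.null(color_by)) {
    if (!color_by %in% names(df) || !is.numeric(df[[color_by]])) {
      stop("unknown or non-numeric color column: ", color_by, call. = FALSE)
    }
    pal <- colorRampPalette(c("#440154", "#31688E", "#35B779", "#FDE725"))
    v <- df[[color_by]]
    bin <- if (length(unique(v)) == 1L) rep(1L, length(v)) else
      cut(v, breaks = 32, labels = FALSE, include.lowest = TRUE)
    cols <- pal(32)[bin]
  }
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  print(lattice::cloud(
    regularity_cv ~ n_parts * sov_boot_median, data = df,
    pch = 19, col = cols, cex = 1.3,
    xlab = "n parts", ylab = "differentiation (boot SoV)",
    zlab = "irregularity (CV)",
    main = if (is.null(color_by)) "Complexity space" else
      paste0("Complexity space (colour: ", color_by, ")")))
  invisible(path)
}
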