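# Outline pipeline: binary silhouette masks -> closed boundary polygons ->
# arc-length resampling -> generalized Procrustes alignment. Downstream the
# aligned outlines feed elliptical Fourier analysis (efa.R).

#' Construct a closed outline
#'
#' An outline is an ordered closed 2D polygon (the closing edge is implicit).
#' Consecutive duplicate vertices are collapsed; the vertex order is stored
#' counterclockwise (positive signed area), reversing the input if needed.
#'
#' @param points two-column numeric matrix of vertices.
#' @param source_id identifier carried through the pipeline.
#' @return Object of class `outline` with elements `points`, `source_id`.
#' @export
outline <- function(points, source_id = "") {
  pts <- as_point_matrix(points)
  if (ncol(pts) != 2L) stop("an outline needs exactly 2 columns",
                            call. = FALSE)
  # collapse consecutive duplicates (including a repeated closing vertex)
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) > 1L && all(pts[1, ] == pts[nrow(pts), ])) {
    pts <- pts[-nrow(pts), , drop = FALSE]
  }
  if (nrow(pts) < 3L) stop("an outline needs at least 3 distinct vertices",
                           call. = FALSE)
  a <- signed_area(pts)
  if (a == 0) stop("outline encloses zero area", call. = FALSE)
  if (a < 0) pts <- pts[nrow(pts):1, , drop = FALSE]
  colnames(pts) <- c("x", "y")
  structure(list(points = pts, source_id = as.character(source_id)),
            class = "outline")
}

#' @export
print.outline <- function(x, ...) {
  cat("<outline> '", x$source_id, "': ", nrow(x$points),
      " vertices, area ", format(signed_area(x$points), digits = 4),
      ", perimeter ", format(outline_perimeter(x), digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Shoelace signed area of a closed polygon
#'
#' Positive for counterclockwise vertex order.
#'
#' @param pts two-column matrix of vertices (implicitly closed).
#' @return Signed area.
#' @export
signed_area <- function(pts) {
  if (inherits(pts, "outline")) pts <- pts$points
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

#' @rdname signed_area
#' @param o an [outline].
#' @export
outline_perimeter <- function(o) {
  pts <- if (inherits(o, "outline")) o$points else o
  closed <- rbind(pts, pts[1, ])
  sum(sqrt(rowSums(diff(closed)^2)))
}

# 8-connected component labelling of a logical matrix (BFS over a stack).
label_components <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nlab <- 0L
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  for (start in which(m)) {
    if (lab[start] != 0L) next
    nlab <- nlab + 1L
    stack <- start
    lab[start] <- nlab
    while (length(stack)) {
      idx <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((idx - 1L) %% nr) + 1L
      cc <- ((idx - 1L) %/% nr) + 1L
      rr <- r + off_r; ccn <- cc + off_c
      ok <- rr >= 1L & rr <= nr & ccn >= 1L & ccn <= nc
      nb <- (ccn[ok] - 1L) * nr + rr[ok]
      nb <- nb[m[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- nlab
        stack <- c(stack, nb)
      }
    }
  }
  lab
}

#' Trace the outline of a binary mask
#'
#' Extracts the closed boundary polygon of the largest 8-connected
#' foreground component of a binary raster, at the 0.5 isolevel between
#' foreground and background pixel centres. Interior holes are ignored (the
#' outer boundary is the contour enclosing the largest area). Pixel
#' `(row r, col c)` (1-based) maps to Cartesian `(x = c - 0.5,
#' y = -(r - 0.5))`, i.e. image rows grow downwards, outlines live in the
#' usual y-up plane; vertices are returned counterclockwise.
#'
#' @param mask numeric or logical matrix; nonzero/`TRUE` = foreground.
#' @param source_id identifier for the resulting outline.
#' @return An [outline].
#' @export
extract_outline <- function(mask, source_id = "") {
  m <- as.matrix(mask)
  if (is.numeric(m)) m <- m > 0
  if (!is.logical(m)) stop("`mask` must be numeric or logical", call. = FALSE)
  m[is.na(m)] <- FALSE
  if (!any(m)) stop("empty mask: no foreground pixels", call. = FALSE)
  lab <- label_components(m)
  sizes <- tabulate(lab)
  biggest <- max(sizes)
  if (sum(sizes == biggest) > 1L) {
    stop("ambiguous mask: ", sum(sizes == biggest),
         " equally-largest components of ", biggest, " pixels",
         call. = FALSE)
  }
  keep <- lab == which.max(sizes)
  nr <- nrow(keep); nc <- ncol(keep)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- keep
  # Cartesian grid of padded pixel centres; y must increase for contourLines
  xs <- (seq_len(nc + 2L)) - 1.5
  ys_desc <- -((seq_len(nr + 2L)) - 1.5)     # y of padded row 1..nr+2
  z <- t(pad)[, (nr + 2L):1, drop = FALSE]   # z[xi, yj], y ascending
  cl <- contourLines(xs, rev(ys_desc), z, levels = 0.5)
  if (!length(cl)) stop("no boundary found", call. = FALSE)
  areas <- vapply(cl, function(cc) abs(signed_area(cbind(cc$x, cc$y))),
                  numeric(1))
  b <- cl[[which.max(areas)]]
  outline(cbind(b$x, b$y), source_id = source_id)
}

#' Resample an outline to equally spaced vertices
#'
#' Places `n_points` vertices at equal arc-length steps along the closed
#' polygon, starting from the original first vertex. Needed to put outlines
#' into point-to-point correspondence before Procrustes alignment.
#'
#' @param o an [outline].
#' @param n_points number of vertices (>= 3).
#' @return An [outline].
#' @export
resample_outline <- function(o, n_points) {
  stopifnot(inherits(o, "outline"), n_points >= 3)
  pts <- rbind(o$points, o$points[1, ])
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total <= 0) stop("degenerate outline of zero length", call. = FALSE)
  t_new <- total * (seq_len(n_points) - 1) / n_points
  outline(cbind(approx(cum, pts[, 1], xout = t_new)$y,
                approx(cum, pts[, 2], xout = t_new)$y),
          source_id = o$source_id)
}

# Deterministic initial start-vertex: after centering, the vertex of maximal
# x (ties: maximal y) leads. Returns the reindexed (uncentered) matrix.
reindex_start <- function(pts) {
  ctr <- sweep(pts, 2, colMeans(pts))
  i <- order(-ctr[, 1], -ctr[, 2])[1]
  if (i > 1L) pts <- pts[c(i:nrow(pts), 1:(i - 1L)), , drop = FALSE]
  pts
}

# Best rigid alignment of X onto M over cyclic start offsets and rotations
# (reflections excluded). Score of an offset under its optimal rotation is
# sqrt(a^2 + b^2) with a = sum(X*M), b = cross term.
align_one <- function(X, M) {
  n <- nrow(X)
  scores <- numeric(n)
  for (o in 0:(n - 1L)) {
    idx <- ((seq_len(n) - 1L + o) %% n) + 1L
    Xo <- X[idx, , drop = FALSE]
    a <- sum(Xo * M)
    b <- sum(Xo[, 1] * M[, 2] - Xo[, 2] * M[, 1])
    scores[o + 1L] <- sqrt(a^2 + b^2)
  }
  o <- which.max(scores) - 1L
  idx <- ((seq_len(n) - 1L + o) %% n) + 1L
  Xo <- X[idx, , drop = FALSE]
  A <- crossprod(Xo, M)
  sv <- svd(A)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  Xo %*% R
}

#' Generalized Procrustes alignment of a set of outlines
#'
#' Removes position, size and orientation differences: each outline is
#' resampled to `n_points` equal arc-length vertices, centred, scaled to
#' unit centroid size, and rotated (no reflections) to best least-squares
#' fit to an iteratively re-estimated mean shape. Because resampled
#' outlines carry no landmarks, the cyclic start offset of each outline is
#' optimised jointly with its rotation, which makes the alignment invariant
#' to how the input happened to be rotated; the deterministic max-x start
#' rule only fixes the initial indexing.
#'
#' @param outlines list of [outline] objects (>= 2).
#' @param n_points vertices per aligned shape (default 200).
#' @param tol convergence tolerance on the mean-shape change
#'   (Frobenius norm, default 1e-8).
#' @param max_iter iteration cap (default 100); non-convergence warns with
#'   the iteration count.
#' @return List of class `procrustes_fit`: `aligned` (named list of
#'   `n_points x 2` matrices), `mean_shape`, `iterations`, `converged`.
#' @export
procrustes_align <- function(outlines, n_points = 200, tol = 1e-8,
                             max_iter = 100) {
  stopifnot(is.list(outlines), length(outlines) >= 2)
  ids <- vapply(outlines, function(o) o$source_id, character(1))
  if (any(!nzchar(ids))) ids[!nzchar(ids)] <- paste0("shape", which(!nzchar(ids)))
  shapes <- lapply(outlines, function(o) {
    p <- resample_outline(o, n_points)$points
    p <- sweep(p, 2, colMeans(p))
    size <- sqrt(sum(p^2))
    if (size == 0) stop("degenerate outline '", o$source_id, "'",
                        call. = FALSE)
    reindex_start(p / size)
  })
  # Seed the mean from the lexicographically first id, not list position:
  # the iteration's fixed point then cannot depend on input order.
  mean_shape <- shapes[[order(ids)[1]]]
  iter <- 0L
  converged <- FALSE
  aligned <- shapes
  while (iter < max_iter) {
    iter <- iter + 1L
    aligned <- lapply(shapes, align_one, M = mean_shape)
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("Procrustes alignment did not converge in ", iter,
            " iterations", call. = FALSE)
  }
  # Canonical pose: the mean orientation coming out of the iteration depends
  # on which shape seeded it, so rotate everything into the mean's principal
  # axes (major axis along x, sense fixed by the sign of the mean's x then y
  # third moment) and reindex all shapes by the canonical mean start vertex.
  # This makes the output invariant to the order of the input list.
  ev <- eigen(stats::cov(mean_shape), symmetric = TRUE)
  G <- ev$vectors
  if (det(G) < 0) G[, 2] <- -G[, 2]
  m <- mean_shape %*% G
  s3 <- sum(m[, 1]^3)
  if (abs(s3) < 1e-12) s3 <- sum(m[, 2]^3)
  flip <- is.finite(s3) && s3 < 0
  if (flip) m <- -m
  i0 <- order(-m[, 1], -m[, 2])[1]
  idx <- if (i0 > 1L) c(i0:nrow(m), 1:(i0 - 1L)) else seq_len(nrow(m))
  mean_shape <- m[idx, , drop = FALSE]
  aligned <- lapply(aligned, function(p) {
    p <- p %*% G
    if (flip) p <- -p
    p[idx, , drop = FALSE]
  })
  names(aligned) <- ids
  structure(list(aligned = aligned, mean_shape = mean_shape,
                 iterations = iter, converged = converged),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat("<procrustes_fit> ", length(x$aligned), " shapes, ",
      nrow(x$mean_shape), " points; ",
      if (x$converged) "converged" else "NOT converged",
      " in ", x$iterations, " iteration(s)\n", sep = "")
  invisible(x)
}
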