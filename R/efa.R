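# Elliptical Fourier analysis of closed outlines (Kuhl-Giardina): each
# outline, parameterized by arc length, is decomposed into per-harmonic
# coefficient quadruples (a_h, b_h, c_h, d_h) plus a DC term (A0, C0).
# Procrustes alignment upstream already removes size/position/orientation,
# so no additional coefficient normalization is applied by default.

#' Elliptical Fourier coefficients of a closed outline
#'
#' Computes the standard elliptic Fourier series of the closed polygon,
#' parameterized by (polygon) arc length: for harmonic h,
#' `x(t) ~ A0 + sum_h a_h cos(2*pi*h*t/T) + b_h sin(2*pi*h*t/T)` and
#' analogously `y(t)` with `c_h`, `d_h`. The DC terms `A0`, `C0` are the
#' exact means of the piecewise-linear curve.
#'
#' @param o an [outline] (or an `n x 2` matrix of closed-polygon vertices).
#' @param H number of harmonics (`1 <= H <= n_vertices/2 - 1`).
#' @param normalize if `TRUE`, apply first-harmonic phase/rotation/size
#'   normalization on top (off by default: redundant after Procrustes).
#' @return Object of class `efa_coefficients`: `coef` (`H x 4` matrix with
#'   columns a, b, c, d), `dc` (`A0`, `C0`), `H`, `source_id`.
#' @export
#' @examples
#' th <- 2 * pi * (0:199) / 200
#' circ <- outline(cbind(cos(th), sin(th)))
#' ef <- efa_coefficients(circ, H = 4)
#' ef$coef[1, ]  # ~ (1, 0, 0, 1)
efa_coefficients <- function(o, H, normalize = FALSE) {
  pts <- if (inherits(o, "outline")) o$points else as_point_matrix(o)
  src <- if (inherits(o, "outline")) o$source_id else ""
  n <- nrow(pts)
  if (H < 1) stop("`H` must be >= 1", call. = FALSE)
  if (H > n / 2 - 1) {
    stop("H = ", H, " exceeds n_points/2 - 1 = ", floor(n / 2 - 1),
         call. = FALSE)
  }
  closed <- rbind(pts, pts[1, ])
  dxy <- diff(closed)
  dt <- sqrt(rowSums(dxy^2))
  if (any(dt == 0)) {
    keep <- dt > 0
    dxy <- dxy[keep, , drop = FALSE]
    dt <- dt[keep]
  }
  t1 <- cumsum(dt)
  t0 <- c(0, t1[-length(t1)])
  total <- t1[length(t1)]
  coef <- matrix(0, H, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (h in seq_len(H)) {
    w <- 2 * pi * h / total
    const <- total / (2 * pi^2 * h^2)
    dcos <- cos(w * t1) - cos(w * t0)
    dsin <- sin(w * t1) - sin(w * t0)
    coef[h, "a"] <- const * sum(dxy[, 1] / dt * dcos)
    coef[h, "b"] <- const * sum(dxy[, 1] / dt * dsin)
    coef[h, "c"] <- const * sum(dxy[, 2] / dt * dcos)
    coef[h, "d"] <- const * sum(dxy[, 2] / dt * dsin)
  }
  # exact mean of the piecewise-linear closed curve
  x0 <- closed[-nrow(closed), 1]; x1 <- closed[-1, 1]
  y0 <- closed[-nrow(closed), 2]; y1 <- closed[-1, 2]
  keep <- sqrt((x1 - x0)^2 + (y1 - y0)^2) > 0
  dc <- c(A0 = sum(((x0 + x1) / 2 * sqrt((x1 - x0)^2 + (y1 - y0)^2))[keep]) / total,
          C0 = sum(((y0 + y1) / 2 * sqrt((x1 - x0)^2 + (y1 - y0)^2))[keep]) / total)
  out <- structure(list(coef = coef, dc = dc, H = as.integer(H),
                        source_id = src),
                   class = "efa_coefficients")
  if (normalize) efa_normalize(out) else out
}

#' First-harmonic normalization of EFA coefficients
#'
#' Standard Kuhl-Giardina normalization: rotates the parameter phase so the
#' first harmonic starts on its semi-major axis, rotates coordinates so that
#' axis lies along x, and scales by the semi-major axis length. Provided as
#' an option; the default pipeline relies on Procrustes alignment instead of
#' double-normalizing.
#'
#' @param ec an `efa_coefficients` object.
#' @return Normalized `efa_coefficients`.
#' @export
efa_normalize <- function(ec) {
  stopifnot(inherits(ec, "efa_coefficients"))
  cf <- ec$coef
  a1 <- cf[1, "a"]; b1 <- cf[1, "b"]; c1 <- cf[1, "c"]; d1 <- cf[1, "d"]
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1),
                       a1^2 + c1^2 - b1^2 - d1^2)
  for (h in seq_len(ec$H)) {
    rot <- matrix(c(cos(h * theta), -sin(h * theta),
                    sin(h * theta), cos(h * theta)), 2, 2)
    m <- matrix(cf[h, ], 2, 2, byrow = TRUE) %*% rot
    cf[h, ] <- as.numeric(t(m))
  }
  a1s <- cf[1, "a"]; c1s <- cf[1, "c"]
  psi <- atan2(c1s, a1s)
  rot2 <- matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2, 2,
                 byrow = TRUE)
  for (h in seq_len(ec$H)) {
    m <- rot2 %*% matrix(cf[h, ], 2, 2, byrow = TRUE)
    cf[h, ] <- as.numeric(t(m))
  }
  scale <- sqrt(cf[1, "a"]^2 + cf[1, "c"]^2)
  if (scale > 0) cf <- cf / scale
  ec$coef <- cf
  ec
}

#' Reconstruct an outline from EFA coefficients
#'
#' Samples the truncated Fourier series at `n_points` equal parameter steps.
#' A coefficient set whose harmonics are all zero reconstructs to a single
#' repeated point, which is not a valid outline; that degenerate case errors.
#'
#' @param ec an `efa_coefficients` object.
#' @param n_points samples along the curve (default 200).
#' @return An [outline].
#' @export
efa_reconstruct <- function(ec, n_points = 200) {
  stopifnot(inherits(ec, "efa_coefficients"), n_points >= 3)
  t <- (seq_len(n_points) - 1) / n_points     # one period
  x <- rep(ec$dc["A0"], n_points)
  y <- rep(ec$dc["C0"], n_points)
  for (h in seq_len(ec$H)) {
    ang <- 2 * pi * h * t
    x <- x + ec$coef[h, "a"] * cos(ang) + ec$coef[h, "b"] * sin(ang)
    y <- y + ec$coef[h, "c"] * cos(ang) + ec$coef[h, "d"] * sin(ang)
  }
  if (all(ec$coef == 0)) {
    stop("all harmonic coefficients are zero: degenerate single-point curve",
         call. = FALSE)
  }
  outline(cbind(x, y), source_id = ec$source_id)
}

#' Per-harmonic and cumulative harmonic power
#'
#' Power of harmonic h is `(a_h^2 + b_h^2 + c_h^2 + d_h^2) / 2`; the
#' cumulative fraction guides the choice of how many harmonics to keep.
#'
#' @param ec an `efa_coefficients` object.
#' @return data.frame with columns `harmonic`, `power`, `cum_fraction`.
#' @export
harmonic_power <- function(ec) {
  stopifnot(inherits(ec, "efa_coefficients"))
  p <- rowSums(ec$coef^2) / 2
  data.frame(harmonic = seq_len(ec$H), power = p,
             cum_fraction = cumsum(p) / sum(p))
}

#' Smallest harmonic count reaching a cumulative power threshold
#'
#' For each outline, finds the smallest H whose cumulative harmonic power
#' reaches `threshold` (computed against `H_max` harmonics), and returns the
#' maximum over the set, so one shared H suffices for every outline.
#'
#' @param outlines list of [outline] objects.
#' @param threshold cumulative power fraction (default 0.99).
#' @param H_max harmonic budget to evaluate against (default 20, capped by
#'   each outline's vertex count).
#' @return Integer H.
#' @export
choose_harmonics <- function(outlines, threshold = 0.99, H_max = 20) {
  stopifnot(is.list(outlines), length(outlines) >= 1)
  hs <- vapply(outlines, function(o) {
    cap <- floor(nrow(o$points) / 2 - 1)
    hp <- harmonic_power(efa_coefficients(o, H = min(H_max, cap)))
    which(hp$cum_fraction >= threshold)[1]
  }, numeric(1))
  if (anyNA(hs)) {
    stop("threshold not reached within H_max harmonics", call. = FALSE)
  }
  as.integer(max(hs))
}

#' Flatten EFA coefficient sets into a part table
#'
#' Each outline becomes one row with `4 * H` variables
#' (`a1, b1, c1, d1, ..., dH`); DC terms are dropped (they encode position
#' only). The resulting [part_table] is ready for [build_morphospace] and
#' [pca_ordinate].
#'
#' @param coeffs list of `efa_coefficients`, all with the same H.
#' @param system_ids character vector, one system label per coefficient set.
#' @param part_ids optional part labels (default: outline `source_id`s, or
#'   sequence numbers).
#' @return A [part_table] with provenance `"efa"`.
#' @export
flatten_to_morphospace <- function(coeffs, system_ids, part_ids = NULL) {
  stopifnot(is.list(coeffs), length(coeffs) >= 1,
            length(system_ids) == length(coeffs))
  hs <- vapply(coeffs, function(ec) ec$H, integer(1))
  if (length(unique(hs)) != 1L) {
    stop("mixed harmonic counts: ", paste(unique(hs), collapse = ", "),
         call. = FALSE)
  }
  H <- hs[1]
  if (is.null(part_ids)) {
    part_ids <- vapply(coeffs, function(ec) ec$source_id, character(1))
    if (any(!nzchar(part_ids))) part_ids <- as.character(seq_along(coeffs))
  }
  vars <- as.vector(t(outer(seq_len(H), c("a", "b", "c", "d"),
                            function(h, l) paste0(l, h))))
  m <- t(vapply(coeffs, function(ec) as.numeric(t(ec$coef)),
                numeric(4 * H)))
  colnames(m) <- vars
  part_table(
    data.frame(system_id = system_ids, part_id = part_ids, m,
               stringsAsFactors = FALSE),
    variables = vars, provenance = "efa")
}
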