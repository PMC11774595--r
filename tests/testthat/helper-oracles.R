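# Independent oracles and small fixture builders shared across tests.
# Each oracle is a deliberately naive reimplementation (explicit loops,
# brute-force enumeration) kept separate from the package's code paths.

# CV of all pairwise distances, by explicit double loop.
oracle_pairwise_cv <- function(pts) {
  n <- nrow(pts)
  d <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- c(d, sqrt(sum((pts[i, ] - pts[j, ])^2)))
    }
  }
  stats::sd(d) / mean(d)
}

# CV of pooled low-order NNDs, by full per-point sort.
oracle_nnd_cv <- function(pts, orders = c(1, 2)) {
  n <- nrow(pts)
  pooled <- c()
  for (i in seq_len(n)) {
    di <- c()
    for (j in seq_len(n)) {
      if (j != i) di <- c(di, sqrt(sum((pts[i, ] - pts[j, ])^2)))
    }
    pooled <- c(pooled, sort(di)[orders])
  }
  stats::sd(pooled) / mean(pooled)
}

# Minimal run-length description length by exhaustive recursive search over
# all literal/run decompositions (no memoisation, cost-pruned).
oracle_rle_min <- function(s) {
  s <- as.character(s)
  n <- length(s)
  best <- Inf
  rec <- function(i, cost) {
    if (cost >= best) return(invisible())
    if (i == n) {
      best <<- cost
      return(invisible())
    }
    rec(i + 1L, cost + 1L)                      # literal
    rem <- n - i
    for (L in seq_len(rem %/% 2L)) {
      block <- s[(i + 1L):(i + L)]
      k <- 1L
      while (i + (k + 1L) * L <= n &&
             identical(s[(i + k * L + 1L):(i + (k + 1L) * L)], block)) {
        k <- k + 1L
        rec(i + k * L, cost + L + 2L + nchar(as.character(k)))
      }
    }
  }
  rec(0L, 0L)
  best
}

# Bootstrap-median oracle sharing the implementation's RNG call pattern but
# with its own variance arithmetic.
oracle_boot_sov_median <- function(pts, reps, seed) {
  n <- nrow(pts)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  vals <- numeric(reps)
  for (r in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    sub <- pts[idx, , drop = FALSE]
    sov <- 0
    for (j in seq_len(ncol(sub))) {
      x <- sub[, j]
      sov <- sov + sum((x - mean(x))^2) / (n - 1)
    }
    vals[r] <- sov
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  stats::median(vals)
}

# A random proper rotation matrix in d dimensions.
random_rotation <- function(d) {
  q <- qr.Q(qr(matrix(rnorm(d * d), d)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# A generic closed test blob (asymmetric, smooth) as an outline.
make_blob <- function(n = 300, id = "blob") {
  th <- 2 * pi * (seq_len(n) - 1) / n
  outline(cbind(cos(th) * (1 + 0.15 * cos(3 * th) + 0.05 * sin(7 * th)),
                sin(th) * (1 + 0.10 * sin(2 * th))), source_id = id)
}

# Filled-disc binary mask of radius r centred in an n x n image.
make_disc_mask <- function(n, r) {
  m <- matrix(0, n, n)
  ctr <- (n + 1) / 2
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if ((i - ctr)^2 + (j - ctr)^2 <= r^2) m[i, j] <- 1
    }
  }
  m
}
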