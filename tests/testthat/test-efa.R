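unit_circle <- function(n = 500) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  outline(cbind(cos(th), sin(th)))
}

test_that("unit circle decomposes into a single unit first harmonic", {
  ef <- efa_coefficients(unit_circle(), H = 5)
  m1 <- matrix(ef$coef[1, ], 2, 2, byrow = TRUE)
  expect_equal(svd(m1)$d, c(1, 1), tolerance = 1e-3)
  expect_true(all(abs(ef$coef[2:5, ]) < 1e-3))
  expect_equal(unname(ef$dc), c(0, 0), tolerance = 1e-9)
})

test_that("a low-eccentricity ellipse is captured by one harmonic", {
  # Single-harmonic exactness holds in the elliptic parameter; under the
  # arc-length parameterization eccentricity leaks into higher harmonics at
  # order (1 - b/a)/8, so the analytic check uses a mild ellipse where the
  # leakage sits well below tolerance (high-eccentricity shapes are covered
  # by the convergence-in-H test below).
  a <- 2; b <- 1.99
  th <- 2 * pi * (0:999) / 1000
  ell <- outline(cbind(a * cos(th), b * sin(th)))
  rec <- efa_reconstruct(efa_coefficients(ell, H = 1), 1000)
  dense <- cbind(a * cos(2 * pi * (0:4999) / 5000),
                 b * sin(2 * pi * (0:4999) / 5000))
  err <- vapply(seq(1, 1000, by = 5), function(i) {
    min(sqrt((dense[, 1] - rec$points[i, 1])^2 +
               (dense[, 2] - rec$points[i, 2])^2))
  }, numeric(1))
  expect_lt(sqrt(mean(err^2)), 1e-3 * a)
})

test_that("reconstruction error is non-increasing in harmonic count", {
  blob <- make_blob()
  target <- resample_outline(blob, 400)$points
  errs <- vapply(c(1, 2, 4, 8, 16), function(H) {
    rec <- efa_reconstruct(efa_coefficients(blob, H = H), 400)
    # correspondence-free: mean distance to nearest target vertex
    mean(vapply(seq_len(400), function(i) {
      min(sqrt((target[, 1] - rec$points[i, 1])^2 +
                 (target[, 2] - rec$points[i, 2])^2))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-6))
  expect_lt(errs[5], 0.01)
})

test_that("coefficient round trips are stable", {
  # exact-speed curve: machine-level round trip
  ef <- efa_coefficients(unit_circle(1000), H = 4)
  ef2 <- efa_coefficients(efa_reconstruct(ef, 4000), H = 4)
  expect_lt(max(abs(ef$coef - ef2$coef)), 1e-6)
  # generic blob: limited by arc-length reparameterization of the
  # truncated series (the truncated curve is no longer traversed at the
  # constant speed its coefficients assumed), not by the transform itself;
  # the drift scales with the squared relative harmonic amplitude
  efb <- efa_coefficients(make_blob(), H = 8)
  efb2 <- efa_coefficients(efa_reconstruct(efb, 4000), H = 8)
  expect_lt(max(abs(efb$coef - efb2$coef)), 5e-3)
})

test_that("coefficient scaling is linear about the DC point", {
  ef <- efa_coefficients(make_blob(), H = 6)
  ef2 <- ef
  ef2$coef <- ef$coef * 2
  r1 <- efa_reconstruct(ef, 100)$points
  r2 <- efa_reconstruct(ef2, 100)$points
  ctr <- matrix(ef$dc, 100, 2, byrow = TRUE)
  expect_equal(r2 - ctr, 2 * (r1 - ctr), tolerance = 1e-9)
  # all-zero harmonics: degenerate single point, refused
  ef0 <- ef
  ef0$coef[] <- 0
  expect_error(efa_reconstruct(ef0), "degenerate")
})

test_that("harmonic power is non-negative with non-decreasing cumulation", {
  hp <- harmonic_power(efa_coefficients(make_blob(), H = 12))
  expect_true(all(hp$power >= 0))
  expect_true(all(diff(hp$cum_fraction) >= -1e-15))
  expect_equal(hp$cum_fraction[12], 1)
  H <- choose_harmonics(list(make_blob(), unit_circle(300)))
  expect_gte(H, 1L)
  expect_lte(H, 20L)
})

test_that("H is capped by the vertex count", {
  o <- outline(simplex_points(3) + 2)  # triangle, 3 vertices
  expect_error(efa_coefficients(o, H = 2), "exceeds")
  expect_error(efa_coefficients(o, H = 0), ">= 1")
})

test_that("flattening produces one 4H-variable row per outline, in order", {
  col <- synthetic_colony("trimorphic", seed = 2)
  coeffs <- lapply(col, efa_coefficients, H = 2)
  tab <- flatten_to_morphospace(coeffs, system_ids = rep("sp1", 5))
  expect_equal(dim(as.data.frame(tab)), c(5L, 2L + 8L))
  expect_equal(part_variables(tab),
               c("a1", "b1", "c1", "d1", "a2", "b2", "c2", "d2"))
  expect_equal(tab$part_id, names(col))
  expect_equal(as.numeric(tab[1, part_variables(tab)]),
               as.numeric(t(coeffs[[1]]$coef)))
  # identical outlines give identical rows
  two <- flatten_to_morphospace(coeffs[c(1, 1)], rep("s", 2),
                                part_ids = c("p1", "p2"))
  expect_equal(as.numeric(two[1, part_variables(two)]),
               as.numeric(two[2, part_variables(two)]))
  # mixed harmonic counts are rejected
  bad <- c(coeffs[1], list(efa_coefficients(col[[2]], H = 3)))
  expect_error(flatten_to_morphospace(bad, rep("s", 2)), "mixed")
})

test_that("mask-to-coefficients pipeline is deterministic and rigid-invariant", {
  # Asymmetric shapes: for (near-)mirror-symmetric outlines the aligned
  # pose is unique only up to that symmetry, so invariance is asserted on
  # generic blobs.
  col <- list(make_blob(300, "p1"),
              outline(cbind(make_blob(260, "")$points[, 1] * 1.3,
                            make_blob(260, "")$points[, 2]), "p2"),
              outline(make_blob(280, "")$points %*%
                        matrix(c(1, 0.25, 0, 1), 2), "p3"),
              outline(make_blob(240, "")$points +
                        0.1 * cbind(sin(3 * seq_len(240)), 0), "p4"))
  run <- function(outs) {
    fit <- procrustes_align(outs, n_points = 150)
    cf <- lapply(names(fit$aligned), function(id)
      efa_coefficients(outline(fit$aligned[[id]], id), H = 6))
    flatten_to_morphospace(cf, system_ids = rep("sp", length(cf)))
  }
  t1 <- run(col)
  t2 <- run(col)
  expect_identical(t1, t2)   # bit-identical rerun
  rot <- matrix(c(0, 1, -1, 0), 2)
  moved <- lapply(col, function(o)
    outline(sweep(o$points %*% rot * 2.5, 2, c(1, 7), "+"), o$source_id))
  t3 <- run(moved)
  v <- part_variables(t1)
  expect_equal(as.matrix(as.data.frame(t3)[, v]),
               as.matrix(as.data.frame(t1)[, v]), tolerance = 1e-6)
})

test_that("first-harmonic normalization standardizes pose and scale", {
  blob <- make_blob()
  rot <- matrix(c(cos(1.1), sin(1.1), -sin(1.1), cos(1.1)), 2)
  moved <- outline(blob$points %*% rot * 4, "m")
  n1 <- efa_normalize(efa_coefficients(blob, H = 6))
  n2 <- efa_normalize(efa_coefficients(moved, H = 6))
  expect_equal(as.numeric(sqrt(n1$coef[1, "a"]^2 + n1$coef[1, "c"]^2)), 1,
               tolerance = 1e-9)
  expect_equal(n1$coef, n2$coef, tolerance = 1e-4)
})
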