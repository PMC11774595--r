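test_that("sum of variances matches hand computation and conventions", {
  expect_equal(sum_of_variances(rbind(c(0, 0), c(2, 0))), 2)  # var({0,2}) = 2
  expect_equal(sum_of_variances(matrix(c(1, 1), 1)), 0)       # single point
  expect_error(sum_of_variances(matrix(numeric(0), 0, 2)), "no points")
})

test_that("sum of variances is rigid-motion invariant and scales as c^2", {
  set.seed(5)
  pts <- matrix(rnorm(150), ncol = 3)
  base <- sum_of_variances(pts)
  for (i in 1:5) {
    rot <- random_rotation(3)
    shift <- rnorm(3, sd = 10)
    moved <- sweep(pts %*% rot, 2, shift, "+")
    expect_lt(abs(sum_of_variances(moved) - base), 1e-9)
  }
  for (c_ in c(0.1, 3, 42)) {
    expect_equal(sum_of_variances(pts * c_), c_^2 * base, tolerance = 1e-12)
  }
})

test_that("pairwise distance CV: analytic cases, degeneracies, invariance", {
  expect_lt(pairwise_distance_cv(simplex_points(3)), 1e-12)
  # collinear 0, 1, 3: distances {1, 2, 3}, sample SD 1, mean 2
  expect_equal(as.numeric(pairwise_distance_cv(cbind(c(0, 1, 3), 0))), 0.5)
  # two parts: one distance, defined as 0 and flagged
  two <- pairwise_distance_cv(rbind(c(0, 0), c(1, 1)))
  expect_equal(as.numeric(two), 0)
  expect_true(attr(two, "degenerate"))
  # coincident points: undefined, not zero
  co <- pairwise_distance_cv(rbind(c(1, 2), c(1, 2), c(1, 2)))
  expect_true(is.na(co))
  expect_true(attr(co, "undefined"))
  # invariance under rigid motion + uniform scale
  set.seed(9)
  pts <- matrix(rnorm(40), ncol = 2)
  v <- pairwise_distance_cv(pts)
  moved <- sweep(pts %*% random_rotation(2) * 7, 2, c(3, -4), "+")
  expect_equal(pairwise_distance_cv(moved), v, tolerance = 1e-9)
})

test_that("nnd CV: lattice zeros, enumerated example, tie handling", {
  expect_equal(as.numeric(nnd_cv(square_lattice(4, 4, 1))), 0)
  expect_equal(as.numeric(nnd_cv(square_lattice(2, 2, 1))), 0)  # unit square
  # collinear 0,1,2,4: pooled NNDs {1,2, 1,1, 1,2, 2,3}
  pooled <- c(1, 2, 1, 1, 1, 2, 2, 3)
  expect_equal(as.numeric(nnd_cv(cbind(c(0, 1, 2, 4), 0))),
               sd(pooled) / mean(pooled))
  expect_error(nnd_cv(rbind(c(0, 0), c(1, 1))), "at least 3")
  # coincident duplicates contribute legitimate zero distances
  with_dup <- nnd_cv(cbind(c(0, 0, 1, 3), 0))
  expect_gt(as.numeric(with_dup), 0)
  all_co <- nnd_cv(matrix(1, 4, 2))
  expect_true(is.na(all_co) && attr(all_co, "undefined"))
})

test_that("nnd and pairwise CV match brute-force oracles on random clouds", {
  set.seed(21)
  for (i in 1:100) {
    n <- sample(4:15, 1)
    d <- sample(2:4, 1)
    pts <- matrix(rnorm(n * d), ncol = d)
    expect_equal(as.numeric(nnd_cv(pts)), oracle_nnd_cv(pts),
                 tolerance = 1e-12)
    expect_equal(as.numeric(pairwise_distance_cv(pts)),
                 oracle_pairwise_cv(pts), tolerance = 1e-12)
  }
})

test_that("regularity dispatch follows parts-vs-dimensions rule", {
  r3 <- regularity_index(simplex_points(3), n_axes = 2)
  expect_equal(r3$method, "all_pairwise")
  r4 <- regularity_index(simplex_points(4), n_axes = 3)
  expect_equal(r4$method, "all_pairwise")
  expect_lt(as.numeric(r4$value), 1e-12)
  set.seed(2)
  r10 <- regularity_index(matrix(rnorm(20), ncol = 2), n_axes = 2)
  expect_equal(r10$method, "nnd_1_2")
})

test_that("on a lattice the low-order NND CV is 0 but all-pairwise CV > 0", {
  lat <- square_lattice(4, 4, 1)
  expect_equal(as.numeric(nnd_cv(lat)), 0)
  expect_gt(as.numeric(pairwise_distance_cv(lat)), 0)
})

test_that("bootstrap SoV is deterministic given seed and matches its oracle", {
  set.seed(3)
  pts <- matrix(rnorm(20), ncol = 2)
  b1 <- bootstrap_sov(pts, reps = 100, seed = 77)
  b2 <- bootstrap_sov(pts, reps = 100, seed = 77)
  expect_identical(b1$replicates, b2$replicates)
  expect_false(identical(
    b1$replicates, bootstrap_sov(pts, reps = 100, seed = 78)$replicates))
  # identical points: every replicate SoV is 0
  expect_equal(bootstrap_sov(matrix(1, 5, 2), reps = 50, seed = 1)$median, 0)
  # independently coded resampler sharing the RNG stream
  expect_equal(b1$median, oracle_boot_sov_median(pts, 100, 77),
               tolerance = 1e-12)
  big <- bootstrap_sov(pts, reps = 10000, seed = 5)
  expect_equal(big$median, oracle_boot_sov_median(pts, 10000, 5),
               tolerance = 1e-12)
  expect_error(bootstrap_sov(pts, reps = 0, seed = 1), "reps")
})

test_that("bootstrap does not disturb the caller's RNG stream", {
  pts <- matrix(seq_len(10), ncol = 2)
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(bootstrap_sov(pts, seed = 9))
  expect_identical(runif(1), a)
})

test_that("complexity profiles assemble the three axes correctly", {
  pts <- rbind(simplex_points(4) + 5, matrix(0, 1, 3))
  space <- morphospace(pts, c(rep("simp", 4), "solo"))
  prof <- complexity_profile(space, "simp", seed = 42)
  expect_equal(prof$n_parts, 4L)
  expect_gt(prof$sov, 0)
  expect_equal(prof$regularity_cv, 0, tolerance = 1e-12)
  expect_equal(prof$regularity_method, "all_pairwise")
  solo <- complexity_profile(space, "solo", seed = 42)
  expect_equal(solo$n_parts, 1L)
  expect_equal(solo$sov, 0)
  expect_true(is.na(solo$regularity_cv))  # undefined, never 0
  expect_error(complexity_profile(space, "nope", seed = 1), "unknown system")
})

test_that("profiles are invariant to rigid motion of the whole system", {
  set.seed(14)
  pts <- matrix(rnorm(24), ncol = 2)
  moved <- sweep(pts %*% random_rotation(2), 2, c(11, -3), "+")
  space <- morphospace(rbind(pts, moved),
                       rep(c("orig", "moved"), each = 12))
  cs <- build_complexity_space(space, reps = 50, seed = 7)
  o <- cs[cs$system_id == "orig", ]
  m <- cs[cs$system_id == "moved", ]
  expect_equal(o$sov, m$sov, tolerance = 1e-9)
  expect_equal(o$regularity_cv, m$regularity_cv, tolerance = 1e-9)
  expect_equal(o$n_parts, m$n_parts)
})

test_that("build_complexity_space equals per-system profiles, stable order", {
  set.seed(6)
  pts <- matrix(rnorm(30), ncol = 2)
  ids <- rep(c("b", "c", "a"), each = 5)
  space <- morphospace(pts, ids)
  cs <- build_complexity_space(space, reps = 30, seed = 2)
  expect_equal(cs$system_id, c("a", "b", "c"))
  for (id in c("a", "b", "c")) {
    one <- complexity_profile(space, id, reps = 30, seed = 2)
    expect_equal(cs[cs$system_id == id, ]$sov_boot_median,
                 one$sov_boot_median)
  }
  # bootstrap streams keyed by system id: relabeling order cannot matter
  space2 <- morphospace(pts[c(6:10, 1:5, 11:15), ],
                        ids[c(6:10, 1:5, 11:15)])
  cs2 <- build_complexity_space(space2, reps = 30, seed = 2)
  expect_equal(cs$sov_boot_median, cs2$sov_boot_median)
})

test_that("part_count counts rows including coincident parts", {
  pts <- rbind(matrix(rnorm(30), ncol = 2), c(0, 0), c(0, 0))
  space <- morphospace(pts, c(rep("x", 15), "y", "y"))
  expect_equal(part_count(space, "x"), 15L)
  expect_equal(part_count(space, "y"), 2L)
  expect_error(part_count(space, "z"), "unknown system")
})

test_that("optional spread variants behave as documented", {
  pts <- rbind(c(0, 0), c(2, 0), c(2, 1))
  expect_equal(sum_of_ranges(pts), 3)
  expect_equal(mean_pairwise_distance(rbind(c(0, 0), c(3, 4))), 5)
  # SoR is orientation-sensitive where SoV is not
  rot <- matrix(c(cos(pi / 4), sin(pi / 4), -sin(pi / 4), cos(pi / 4)), 2)
  expect_false(isTRUE(all.equal(sum_of_ranges(pts %*% rot),
                                sum_of_ranges(pts))))
  expect_equal(sum_of_variances(pts %*% rot), sum_of_variances(pts),
               tolerance = 1e-12)
})
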