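test_that("input fractions normalise counts to total inputs", {
  expect_equal(unname(input_fractions(c(A = 50, B = 50))), c(0.5, 0.5))
  expect_equal(unname(input_fractions(c(A = 0, B = 12))), c(0, 1))
  f <- input_fractions(c(a = 3, b = 11, c = 7, d = 0))
  expect_lt(abs(sum(f) - 1), 1e-12)
  expect_error(input_fractions(c(a = 0, b = 0)), "empty")
})

test_that("visual fractions are scoped to visual areas only", {
  v <- visual_normalized_fractions(c(V1 = 90, LM = 10))
  expect_equal(unname(v[c("V1", "LM")]), c(0.9, 0.1))
  expect_equal(sum(v), 1)
  with_nonvis <- visual_normalized_fractions(c(V1 = 90, LM = 10, RSP = 400))
  expect_equal(v, with_nonvis)
  und <- visual_normalized_fractions(c(RSP = 10))
  expect_true(isTRUE(attr(und, "undefined")))
  expect_true(all(is.na(und)))
})

test_that("hexagonal binning conserves counts deterministically", {
  h1 <- hexbin_density(rep(1234.5, 3), rep(-87.2, 3))
  expect_equal(nrow(h1), 1)
  expect_equal(h1$count, 3L)
  h0 <- hexbin_density(numeric(0), numeric(0))
  expect_equal(nrow(h0), 0)
  pts <- with_seed(7, cbind(runif(5000, 0, 5000), runif(5000, 0, 5000)))
  h <- hexbin_density(pts[, 1], pts[, 2])
  expect_equal(sum(h$count), 5000L)
  # translation equivariance: shifting points and origin together
  h_shift <- hexbin_density(pts[, 1] + 1000, pts[, 2] - 500,
                            origin = c(1000, -500))
  expect_equal(h$q, h_shift$q)
  expect_equal(h$r, h_shift$r)
  expect_equal(h$count, h_shift$count)
  expect_equal(h_shift$cx, h$cx + 1000)
})

test_that("uniform hex counts are Poisson-dispersed", {
  pts <- with_seed(31, cbind(runif(20000, 0, 6000), runif(20000, 0, 6000)))
  h <- hexbin_density(pts[, 1], pts[, 2], width = 300)
  # drop partial edge bins: keep bins with centres well inside the window
  core <- h[h$cx > 400 & h$cx < 5600 & h$cy > 400 & h$cy < 5600, ]
  disp <- stats::var(core$count) / mean(core$count)
  expect_gt(disp, 0.7)
  expect_lt(disp, 1.3)
})

test_that("distances are Euclidean and translation invariant", {
  cells <- data.frame(x_um = c(0, 300), y_um = c(0, 400))
  d <- distances_to_target(cells, c(0, 0))
  expect_equal(d, c(0, 500))
  shifted <- data.frame(x_um = cells$x_um + 77, y_um = cells$y_um - 13)
  expect_equal(distances_to_target(shifted, c(77, -13)), d)
  expect_error(distances_to_target(cells, c(NA, 0)), "finite")
})

test_that("within-radius proportions use a closed disc", {
  p <- proportion_within_radius(c(100, 300, 500), 400)
  expect_equal(p$proportion, 2 / 3)
  expect_equal(proportion_within_radius(c(100, 400), 400)$proportion, 1)
  expect_equal(proportion_within_radius(c(100, 300, 500), Inf)$proportion, 1)
  expect_equal(proportion_within_radius(c(100, 300), 0)$proportion, 0)
  empty <- proportion_within_radius(numeric(0))
  expect_true(empty$undefined)
})

test_that("distance densities are proper reflected KDEs", {
  x <- with_seed(13, abs(rnorm(5000, 2000, 200)))
  d <- distance_density(x)
  expect_true(all(d$density >= 0))
  expect_lt(abs(grid_integral(d) - 1), 0.01)
  mode <- d$grid[which.max(d$density)]
  expect_lt(abs(mode - 2000), 100)
  bim <- distance_density(c(rep(10, 50), rep(5000, 50)))
  expect_lt(abs(grid_integral(bim) - 1), 0.01)
  const <- distance_density(rep(500, 20))
  expect_lt(abs(const$grid[which.max(const$density)] - 500), 20)
  expect_error(distance_density(5), "at least 2")
})

test_that("pooled mean/SEM and median/MAD match brute-force formulas", {
  s <- pooled_mean_sem(c(0, 100))
  expect_equal(s$mean, 50)
  expect_equal(s$sem, 50)
  expect_equal(pooled_mean_sem(rep(4.2, 6))$sem, 0)
  x <- with_seed(3, rnorm(37, 10, 4))
  s2 <- pooled_mean_sem(x)
  expect_equal(s2$mean, sum(x) / length(x))
  expect_equal(s2$sem,
               sqrt(sum((x - mean(x))^2) / (length(x) - 1)) / sqrt(length(x)))
  expect_true(pooled_mean_sem(3)$undefined_sem)

  mm <- median_mad(c(1, 2, 3, 4, 100))
  expect_equal(mm$median, 3)
  expect_equal(mm$mad, 1)
  expect_equal(median_mad(rep(7, 5)), list(median = 7, mad = 0))
  expect_equal(median_mad(42), list(median = 42, mad = 0))
  y <- with_seed(4, rexp(51))
  mm2 <- median_mad(y)
  expect_equal(mm2$mad, stats::median(abs(y - stats::median(y))))
})

test_that("relative-strength matrices are column-normalised to their max", {
  m <- cbind(a = c(2, 4, 8), b = c(1, 1, 1))
  rs <- relative_strength_matrix(m)
  expect_equal(unname(rs[, "a"]), c(0.25, 0.5, 1))
  expect_equal(relative_strength_matrix(diag(3)), diag(3),
               ignore_attr = TRUE)
  expect_equal(relative_strength_matrix(m * c(1, 1, 1)),
               relative_strength_matrix(cbind(a = 5 * m[, 1], b = m[, 2])),
               ignore_attr = TRUE)
  z <- cbind(a = c(0, 0), b = c(1, 2))
  rz <- relative_strength_matrix(z)
  expect_equal(unname(rz[, "a"]), c(0, 0))
  expect_equal(attr(rz, "zero_columns"), "a")
  expect_true(all(rs >= 0 & rs <= 1))
})
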