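test_that("permutation p-values use add-one sampling and plain enumeration", {
  expect_equal(permutation_pvalue(10, rep(1, 9), tail = "upper"), 1 / 10)
  expect_equal(permutation_pvalue(0, rep(1, 9), tail = "upper"), 1)
  expect_equal(permutation_pvalue(10, rep(1, 9999), tail = "upper"), 1e-4)
  expect_equal(permutation_pvalue(10, rep(1, 10000), tail = "upper"),
               1 / 10001)
  # exhaustive mode: plain proportion over the full enumeration
  expect_equal(permutation_pvalue(5, c(1, 2, 3, 4, 5), tail = "upper",
                                  exhaustive = TRUE), 1 / 5)
  expect_equal(permutation_pvalue(1, c(1, 2, 3, 4, 5), tail = "lower",
                                  exhaustive = TRUE), 1 / 5)
  expect_error(permutation_pvalue(1, numeric(0)), "empty")
})

test_that("the 10,000-shuffle reporting floor matches the convention", {
  p <- permutation_pvalue(1e9, rnorm(10000), tail = "upper")
  expect_equal(p, 1 / 10001)
  expect_equal(signif(p, 2), 1.0e-4)
  expect_equal(format_pvalue(p, 10000), "p < 1.0e-04")
  expect_match(format_pvalue(0.0432, 10000), "p = 0.0432")
})

test_that("Benjamini-Hochberg adjustment is step-up, monotone, idempotent", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  p <- with_seed(5, runif(20)^2)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-15))
  # independent step-up recomputation
  m <- length(p)
  qs <- rev(cummin(rev(sort(p) * m / seq_len(m))))
  expect_equal(q[o], pmin(1, qs))
  expect_error(bh_adjust(c(0, 0.5)), "\\(0, 1\\]")
})

test_that("Kruskal-Wallis and Dunn-Sidak reproduce hand computations", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$H, 7.2)
  expect_equal(kw$df, 2)
  same <- kruskal_wallis(list(c(1, 3, 5), c(2, 4, 6)))
  expect_lt(same$H, 1)
  expect_gt(same$p, 0.3)
  expect_true(kruskal_wallis(list(c(2, 2), c(2, 2)))$degenerate)
  shifted <- kruskal_wallis(list(rnorm2 <- 1:8, 101:108))
  expect_lt(shifted$p, 0.01)

  expect_equal(sidak_adjust(0.04, 3), 0.115264)
  expect_equal(sidak_adjust(0, 5), 0)
  expect_equal(sidak_adjust(0.3, 1), 0.3)

  g <- list(a = c(1, 2, 3, 4), b = c(3, 4, 5, 6), c = c(30, 31, 32, 33))
  ds <- dunn_sidak(g)
  expect_false(ds$gated)
  expect_equal(nrow(ds$pairs), 3)
  expect_equal(ds$pairs$p_sidak,
               pmin(1, 1 - (1 - ds$pairs$p_raw)^3))
  # gatekeeping: indistinguishable groups yield no post hoc comparisons
  null_g <- with_seed(2, list(a = rnorm(8), b = rnorm(8)))
  kwp <- kruskal_wallis(null_g)$p
  ds2 <- dunn_sidak(null_g, gate_alpha = min(0.99 * kwp, 0.05))
  expect_true(ds2$gated)
  expect_equal(nrow(ds2$pairs), 0)
})

test_that("Monte-Carlo Fisher matches the exact enumeration oracle", {
  tab <- matrix(c(2, 1, 1, 2), 2)
  expect_equal(fisher_exact_enum(tab), 1, tolerance = 1e-12)
  fm <- fisher_mc(tab, n_shuffles = 2000, seed = 4)
  expect_equal(fm$p, 1)

  set.seed(60)
  n_ok <- 0L; n_tab <- 40L
  for (i in seq_len(n_tab)) {
    repeat {
      t2 <- matrix(rmultinom(1, sample(10:30, 1), rep(1, 6)), nrow = 2)
      if (all(rowSums(t2) > 0) && all(colSums(t2) > 0)) break
    }
    exact <- fisher_exact_enum(t2)
    mc <- fisher_mc(t2, n_shuffles = 4000, seed = 1000L + i)
    if (abs(mc$p - exact) <= 3 * max(mc$mc_se, 1 / 4000)) n_ok <- n_ok + 1L
    # cross-check the enumeration oracle itself against fisher.test
    if (i <= 5) {
      expect_equal(exact, stats::fisher.test(t2)$p.value, tolerance = 1e-6)
    }
  }
  expect_gte(n_ok / n_tab, 0.95)

  expect_error(fisher_mc(matrix(1:3, 1)), "at least 2 rows")
  expect_error(fisher_mc(matrix(c(1, 0, 2, 0), 2), 100), "zero row or column")
})

test_that("shuffle-count sizing reproduces the precision formula", {
  expect_equal(signif(mc_shuffles_needed(1e-4, 0.95), 2), 9.6e7)
  expect_equal(mc_shuffles_needed(0.5, 0.95), 4)
  n1 <- mc_shuffles_needed(0.01, 0.95)
  n2 <- mc_shuffles_needed(0.005, 0.95)
  expect_equal(n2 / n1, 4, tolerance = 1e-3)  # halving h quadruples N
  expect_error(mc_shuffles_needed(0), "half_width")
})

test_that("Pearson chi-squared independence matches hand computation", {
  even <- chi2_independence(matrix(10, 2, 2))
  expect_equal(even$chi2, 0)
  expect_equal(even$p, 1)
  diag2 <- chi2_independence(matrix(c(20, 0, 0, 20), 2))
  expect_equal(diag2$chi2, 40)
  expect_equal(diag2$df, 1)
  m <- matrix(c(5, 10, 20, 8, 2, 9), 2, byrow = TRUE)
  expect_equal(chi2_independence(m)$chi2,
               chi2_independence(m[2:1, ])$chi2)  # row-swap invariance
  expect_error(chi2_independence(matrix(c(1, 2, 0, 0, 3, 0), 3)),
               "zero row or column")
})

test_that("proportion standard errors follow the binomial formula", {
  expect_equal(se_proportion(0.5, 100), 0.05)
  expect_equal(se_proportion(0, 50), 0)
  expect_equal(se_proportion(0.2, 25), 0.08)
  expect_error(se_proportion(1.2, 10), "p_hat")
})

test_that("exhaustive shuffles enumerate one value per candidate combination", {
  cfg <- fast_config(seed = 31L)
  e <- make_experiment(cfg, "AL", "AL1")
  stat <- function(exp, target, ref) {
    proportion_within_radius(
      distances_to_target(exp$cells[exp$cells$layer == "L6", ], ref),
      400)$proportion
  }
  null1 <- shuffle_null(list(e), stat, exhaustive = TRUE)
  expect_length(null1$values, 5)
  expect_true(null1$exhaustive)
  # observed computed with the same centroid rule appears in the null
  obs <- stat(e, "AL", area_centroid(e$parcellation, "AL"))
  expect_true(any(abs(null1$values - obs) < 1e-12))
  e2 <- make_experiment(cfg, "PM", "PM1")
  null2 <- shuffle_null(list(e, e2), stat, exhaustive = TRUE)
  expect_length(null2$values, 25)
})

test_that("a target-independent statistic gives a constant null", {
  cfg <- fast_config(seed = 32L)
  e <- make_experiment(cfg, "RL", "RL1")
  null <- shuffle_null(list(e), function(exp, target, ref) nrow(exp$cells),
                       n_shuffles = 50, seed = 2)
  expect_true(all(null$values == nrow(e$cells)))
})

test_that("independent shuffle seeds give consistent null distributions", {
  cfg <- fast_config(seed = 33L)
  exps <- list(make_experiment(cfg, "AM", "AM1"),
               make_experiment(cfg, "LM", "LM1"))
  stat <- function(exp, target, ref) {
    proportion_within_radius(
      distances_to_target(exp$cells[exp$cells$layer == "L6", ], ref),
      400)$proportion
  }
  n1 <- shuffle_null(exps, stat, n_shuffles = 400, seed = 1)
  n2 <- shuffle_null(exps, stat, n_shuffles = 400, seed = 2)
  expect_false(identical(n1$values, n2$values))
  ks <- suppressWarnings(stats::ks.test(n1$values, n2$values))
  expect_gt(ks$p.value, 0.01)
  # determinism given the seed
  n1b <- shuffle_null(exps, stat, n_shuffles = 400, seed = 1)
  expect_identical(n1$values, n1b$values)
})

test_that("shuffling fails loudly when a candidate area is missing", {
  cfg <- fast_config(seed = 34L)
  e <- make_experiment(cfg, "AL", "AL1")
  e$parcellation$areas[["PM"]] <- NULL
  expect_error(
    shuffle_null(list(e), function(exp, target, ref) 0, n_shuffles = 5),
    "missing candidate area.*PM")
})

test_that("planted reciprocity is detected by the one-tailed shuffle test", {
  cfg <- fast_config(seed = 35L, n_L6_cells = 600L, n_L5_cells = 66L,
                     l6_reciprocal_multiplier = 3)
  exps <- lapply(1:3, function(i) make_experiment(cfg, "AL", paste0("AL", i)))
  res <- reciprocity_test(exps, "L6", n_shuffles = 500, seed = 9)
  expect_equal(res$tail, "upper")
  expect_lt(res$p_raw, 0.05)
  print_out <- capture.output(print(res))
  expect_true(any(grepl("Shuffled-target", print_out)))
})

test_that("adjust_tests fills BH-adjusted p-values across a family", {
  cfg <- fast_config(seed = 36L, n_L6_cells = 200L, n_L5_cells = 20L)
  by_t <- lapply(c("PM", "AL"), function(t) {
    list(make_experiment(cfg, t, paste0(t, "x")))
  })
  tests <- lapply(by_t, function(g) {
    reciprocity_test(g, "L6", n_shuffles = 99, seed = 3)
  })
  adj <- adjust_tests(tests)
  p <- vapply(adj, `[[`, numeric(1), "p_raw")
  expect_equal(vapply(adj, `[[`, numeric(1), "p_adjusted"), bh_adjust(p))
  expect_true(all(vapply(adj, `[[`, "", "adjustment") == "BH"))
})
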