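test_that("zero jitter reproduces the template map exactly", {
  cfg <- fast_config()
  parc <- make_flatmap(cfg, "A1")
  template <- template_flatmap_areas()
  expect_identical(names(parc$areas), names(template))
  for (nm in names(template)) {
    expect_equal(unname(parc$areas[[nm]]), unname(template[[nm]]))
  }
})

test_that("flatmaps are deterministic and jitter is bounded", {
  cfg <- synth_config(seed = 5, border_jitter_um = 50)
  p1 <- make_flatmap(cfg, "B2")
  p2 <- make_flatmap(cfg, "B2")
  expect_identical(p1$areas, p2$areas)
  p3 <- make_flatmap(cfg, "B3")
  expect_false(identical(p1$areas, p3$areas))
  template <- template_flatmap_areas()
  for (nm in names(template)) {
    d <- sqrt(rowSums((p1$areas[[nm]] - template[[nm]])^2))
    expect_true(all(d <= 50 + 1e-9))
  }
  expect_silent(validate_parcellation(p1))
})

test_that("experiments are deterministic and conserve configured counts", {
  cfg <- fast_config()
  e1 <- make_experiment(cfg, "AL", "AL1")
  e2 <- make_experiment(cfg, "AL", "AL1")
  expect_identical(e1$cells, e2$cells)
  expect_identical(e1$brainwide, e2$brainwide)
  expect_identical(e1$sc_cells, e2$sc_cells)
  expect_equal(sum(e1$cells$layer == "L6"), cfg$n_L6_cells)
  expect_equal(sum(e1$cells$layer == "L5"), cfg$n_L5_cells)
  expect_equal(sum(e1$brainwide), cfg$n_brainwide)
  expect_equal(sum(e1$starters), cfg$n_starters)
  # per-area cells sum to the totals
  expect_equal(nrow(e1$cells), cfg$n_L6_cells + cfg$n_L5_cells)
  expect_true(e1$target %in% names(e1$parcellation$areas))
  site_in <- points_in_polygon(e1$injection_site[1], e1$injection_site[2],
                               e1$parcellation$areas[["AL"]])
  expect_true(site_in)
})

test_that("layer counts keep the 9:1 L6CT:L5CT ratio in fixed-counts mode", {
  cfg <- fast_config(n_L6_cells = 900L, n_L5_cells = 100L)
  e <- make_experiment(cfg, "PM", "PM1")
  expect_equal(sum(e$cells$layer == "L6") / sum(e$cells$layer == "L5"), 9)
})

test_that("multiplier 1 keeps area-weighted uniform density (calibration)", {
  # all cells in V1; the disc around the V1 centroid lies fully inside, so
  # the within-radius expectation is the analytic area fraction
  cfg <- fast_config(n_L6_cells = 100L, n_L5_cells = 0L,
                     areal_weights_L6 = c(V1 = 1))
  centroid <- polygon_centroid(template_flatmap_areas()$V1)
  v1_area <- 1800 * 2000
  p_expect <- pi * 400^2 / v1_area
  hits <- 0L; total <- 0L
  for (i in 1:100) {
    e <- make_experiment(cfg, "LM", paste0("rep", i))
    d <- distances_to_target(e$cells, centroid)
    hits <- hits + sum(d <= 400)
    total <- total + length(d)
  }
  se <- sqrt(p_expect * (1 - p_expect) / total)
  expect_lt(abs(hits / total - p_expect), 3 * se)
})

test_that("reciprocal multiplier 3 triples the within-radius intensity", {
  base_cfg <- fast_config(seed = 21L, n_L6_cells = 2000L, n_L5_cells = 0L)
  enr_cfg <- fast_config(seed = 21L, n_L6_cells = 2000L, n_L5_cells = 0L,
                         l6_reciprocal_multiplier = 3)
  e0 <- make_experiment(base_cfg, "AM", "AM1")
  e3 <- make_experiment(enr_cfg, "AM", "AM1")
  # same stream: base placement and injection site are identical
  expect_equal(e0$injection_site, e3$injection_site)
  d0 <- distances_to_target(e0$cells, e0$injection_site)
  d3 <- distances_to_target(e3$cells, e3$injection_site)
  k <- sum(d0 <= 400)
  expect_gt(k, 0)
  # multiplier 3 adds exactly two superposed duplicates per in-disc cell
  expect_equal(sum(d3 <= 400 + 1e-9), 3 * k)
  expect_equal(nrow(e3$cells), nrow(e0$cells) + 2 * k)
  p0 <- k / nrow(e0$cells)
  expect_gt(mean(d3 <= 400), p0)
})

test_that("multiplier below 1 thins the within-radius intensity", {
  base_cfg <- fast_config(seed = 22L, n_L5_cells = 1000L, n_L6_cells = 0L)
  dep_cfg <- fast_config(seed = 22L, n_L5_cells = 1000L, n_L6_cells = 0L,
                         l5_reciprocal_multiplier = 0.2)
  e0 <- make_experiment(base_cfg, "RL", "RL1")
  e2 <- make_experiment(dep_cfg, "RL", "RL1")
  k0 <- sum(distances_to_target(e0$cells, e0$injection_site) <= 400)
  k2 <- sum(distances_to_target(e2$cells, e2$injection_site) <= 400)
  expect_lt(k2, k0)
  expect_lt(abs(k2 - 0.2 * k0), 3 * sqrt(k0 * 0.2 * 0.8) + 1)
})

test_that("SC sample respects degenerate, uniform and shifted theta", {
  cfg0 <- fast_config(sc_theta_params = list(
    PM = list(location = 90, scale = 0), AM = list(location = 45, scale = Inf),
    RL = list(location = 45, scale = 20), AL = list(location = 75, scale = 15),
    LM = list(location = 45, scale = 15)))
  sc_pm <- make_sc_sample(cfg0, "PM", n = 100)
  expect_true(all(abs(sc_pm$theta_true - 90) < 1e-9))
  expect_true(all(abs(compute_theta(sc_pm) - 90) < 1e-6))
  sc_am <- make_sc_sample(cfg0, "AM", n = 4000)
  expect_lt(abs(mean(sc_am$theta_true) - 45), 3 * (90 / sqrt(12)) / sqrt(4000))
  # rank-sum comparison detects a 75 vs 45 degree shift at n = 500
  sc_al <- make_sc_sample(cfg0, "AL", n = 500)
  sc_lm <- make_sc_sample(cfg0, "LM", n = 500)
  w <- stats::wilcox.test(sc_al$theta_true, sc_lm$theta_true)
  expect_lt(w$p.value, 1e-6)
  expect_true(all(sc_al$theta_true >= 0 & sc_al$theta_true <= 90))
  expect_true(all(sc_al$ap_mm >= -4.80 & sc_al$ap_mm <= -2.80))
  expect_true(all(sc_al$layer %in% SC_LAYERS))
})

test_that("section stacks store recoverable ground truth", {
  cfg <- fast_config(landmark_noise_um = 0)
  stack <- make_section_stack(cfg, 4)
  expect_length(stack$landmarks, 3)
  expect_length(stack$truth, 3)
  for (k in 1:3) {
    lm <- stack$landmarks[[k]]
    tgt <- apply_affine(stack$truth[[k]], cbind(lm$xa, lm$ya))
    expect_equal(unname(cbind(lm$xb, lm$yb)), unname(tgt), tolerance = 1e-12)
  }
  expect_error(make_section_stack(cfg, 1), "n_sections")
  expect_error(make_section_stack(fast_config(n_landmarks = 2L), 3),
               "3 landmarks")
})

test_that("config validation rejects malformed probability vectors", {
  expect_error(synth_config(starter_weights = c(pulvinar = 0.9, LD = 0.2)),
               "sum to 1")
  expect_error(synth_config(reciprocity_radius_um = 0), "must be > 0")
  expect_error(synth_config(l6_reciprocal_multiplier = -1), ">= 0")
  expect_error(make_experiment(fast_config(), "XX", "a"), "not in config")
})
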