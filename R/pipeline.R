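# End-to-end pipeline over synthetic experiments: simulate -> flatten ->
# assign -> quantify -> scpolar -> stats. Writes diffable text outputs
# (CSV/GeoJSON/JSON) plus a manifest with checksums so reruns with the same
# config and seed are verifiably identical.

#' Run the full analysis pipeline on synthetic experiments
#'
#' @param config A `synth_config`, or a path to a YAML file whose fields
#'   are `synth_config()` arguments (plus optional `n_shuffles`).
#' @param outdir Output directory (created if needed).
#' @param n_shuffles Shuffles for the permutation stage.
#' @return A run manifest (list), invisibly written to `manifest.json`.
#' @export
run_pipeline <- function(config, outdir, n_shuffles = 1000) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    if (!is.null(raw$n_shuffles)) {
      n_shuffles <- raw$n_shuffles
      raw$n_shuffles <- NULL
    }
    config <- do.call(synth_config, raw)
  }
  if (!inherits(config, "synth_config")) {
    stop("config must be a synth_config or a YAML path")
  }
  if (length(config$targets) == 0) stop("config has no targets")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  stages <- list()

  # -- simulate ---------------------------------------------------------
  exps <- make_experiments(config)
  cells <- do.call(rbind, lapply(exps, `[[`, "cells"))
  rownames(cells) <- NULL
  f_cells <- file.path(outdir, "cells.csv")
  write_cells(cells, f_cells)
  for (e in exps) {
    f <- file.path(outdir, paste0("parcellation_", e$animal_id, ".geojson"))
    write_parcellation(e$parcellation, f)
    files <- c(files, f)
  }
  starters <- do.call(rbind, lapply(exps, function(e) {
    data.frame(animal_id = e$animal_id, target = e$target,
               nucleus = names(e$starters), count = as.integer(e$starters))
  }))
  f_starters <- file.path(outdir, "starters.csv")
  utils::write.csv(starters, f_starters, row.names = FALSE)
  brainwide <- do.call(rbind, lapply(exps, function(e) {
    data.frame(animal_id = e$animal_id, target = e$target,
               region = names(e$brainwide), count = as.integer(e$brainwide))
  }))
  f_bw <- file.path(outdir, "brainwide.csv")
  utils::write.csv(brainwide, f_bw, row.names = FALSE)
  sc <- do.call(rbind, lapply(exps, function(e) {
    cbind(animal_id = e$animal_id, e$sc_cells)
  }))
  f_sc <- file.path(outdir, "sc_cells.csv")
  utils::write.csv(sc, f_sc, row.names = FALSE)
  files <- c(files, f_cells, f_starters, f_bw, f_sc)
  stages$simulate <- "ok"

  # -- flatten ----------------------------------------------------------
  stack <- make_section_stack(config, n_sections = 6)
  flat <- flatten_stack(stack)
  rms <- vapply(seq_along(stack$landmarks), function(k) {
    truth_acc <- Reduce(compose_affine, stack$truth[seq_len(k)])
    src <- cbind(stack$landmarks[[k]]$xa, stack$landmarks[[k]]$ya)
    sqrt(mean(rowSums((apply_affine(flat[[k + 1]], src) -
                         apply_affine(truth_acc, src))^2)))
  }, numeric(1))
  f_tr <- file.path(outdir, "section_transforms.json")
  jsonlite::write_json(
    list(schema_version = SCHEMA_VERSION,
         transforms = lapply(flat, function(a) a$matrix),
         surface_frame_rms_um = rms),
    f_tr, auto_unbox = TRUE, digits = NA)
  files <- c(files, f_tr)
  stages$flatten <- "ok"

  # -- assign -----------------------------------------------------------
  bands <- layer_bands(config$l5_top_um, config$l5_bottom_um)
  assigned <- do.call(rbind, lapply(exps, function(e) {
    cc <- e$cells
    cc <- assign_area(cc, e$parcellation)
    assign_layer(cc, bands)
  }))
  rownames(assigned) <- NULL
  f_assigned <- file.path(outdir, "cells_assigned.csv")
  write_cells(assigned, f_assigned)
  qc <- lapply(exps, qc_experiment)
  f_qc <- file.path(outdir, "qc_report.json")
  jsonlite::write_json(
    list(schema_version = SCHEMA_VERSION,
         experiments = lapply(qc, function(q) {
           list(pass = q$pass, pulvinar_fraction = q$pulvinar_fraction,
                reasons = q$reasons)
         })),
    f_qc, auto_unbox = TRUE, digits = NA)
  files <- c(files, f_assigned, f_qc)
  stages$assign <- "ok"

  # -- quantify ---------------------------------------------------------
  fracs <- do.call(rbind, lapply(exps, function(e) {
    fr <- input_fractions(e$brainwide)
    data.frame(animal_id = e$animal_id, target = e$target,
               region = names(fr), fraction = as.numeric(fr))
  }))
  f_fr <- file.path(outdir, "fractions.csv")
  utils::write.csv(fracs, f_fr, row.names = FALSE)
  vis <- do.call(rbind, lapply(exps, function(e) {
    do.call(rbind, lapply(c("L5", "L6"), function(ly) {
      counts <- table(e$cells$area[e$cells$layer == ly])
      vf <- visual_normalized_fractions(counts)
      data.frame(animal_id = e$animal_id, target = e$target, layer = ly,
                 area = names(vf), fraction = as.numeric(vf))
    }))
  }))
  f_vis <- file.path(outdir, "visual_fractions.csv")
  utils::write.csv(vis, f_vis, row.names = FALSE)
  dists <- do.call(rbind, lapply(exps, function(e) {
    d <- distances_to_target(e$cells, e$injection_site)
    data.frame(animal_id = e$animal_id, target = e$target,
               layer = e$cells$layer, distance_um = d)
  }))
  f_d <- file.path(outdir, "distances.csv")
  utils::write.csv(dists, f_d, row.names = FALSE)
  hx <- hexbin_density(exps[[1]]$cells$x_um, exps[[1]]$cells$y_um)
  f_hx <- file.path(outdir, "hexbins.csv")
  utils::write.csv(as.data.frame(hx), f_hx, row.names = FALSE)
  files <- c(files, f_fr, f_vis, f_d, f_hx)
  stages$quantify <- "ok"

  # -- scpolar ----------------------------------------------------------
  pooled <- pool_by_target(exps)
  f_theta <- file.path(outdir, "theta.csv")
  utils::write.csv(pooled[, c("cell_id", "animal_id", "target", "ap_bin",
                              "theta_deg", "layer", "depth_class")],
                   f_theta, row.names = FALSE)
  pdfs <- do.call(rbind, lapply(split(pooled, pooled$target), function(gg) {
    if (nrow(gg) < 2) return(NULL)
    pdf <- theta_pdf(gg$theta_deg, n_grid = 181)
    data.frame(target = gg$target[1], grid_deg = pdf$grid,
               density = pdf$density)
  }))
  f_pdf <- file.path(outdir, "theta_pdf.csv")
  utils::write.csv(pdfs, f_pdf, row.names = FALSE)
  files <- c(files, f_theta, f_pdf)
  stages$scpolar <- "ok"

  # -- stats ------------------------------------------------------------
  by_target <- split(exps, vapply(exps, `[[`, "", "target"))
  run_family <- function(layer) {
    tests <- lapply(names(by_target), function(t) {
      reciprocity_test(by_target[[t]], layer = layer,
                       radius_um = config$reciprocity_radius_um,
                       n_shuffles = n_shuffles,
                       seed = derive_seed(config$seed, "shuffle", layer, t),
                       candidates = config$targets)
    })
    names(tests) <- names(by_target)
    adjust_tests(tests)
  }
  res <- list(L6 = run_family("L6"), L5 = run_family("L5"))
  f_res <- file.path(outdir, "results.json")
  jsonlite::write_json(
    list(schema_version = SCHEMA_VERSION,
         conventions = list(distance_reference = "injection site (observed); shuffled target centroid (null)",
                            shuffle_space = "uniform over candidate HVAs, original included",
                            adjustment = "Benjamini-Hochberg"),
         tests = lapply(res, function(fam) {
           lapply(fam, function(t) {
             list(statistic = t$statistic, observed = t$observed,
                  n_shuffles = t$n_shuffles, tail = t$tail,
                  p_raw = t$p_raw, p_adjusted = t$p_adjusted,
                  reported = format_pvalue(t$p_raw, t$n_shuffles),
                  seed = t$seed)
           })
         })),
    f_res, auto_unbox = TRUE, digits = NA)
  files <- c(files, f_res)
  stages$stats <- "ok"

  # -- manifest ---------------------------------------------------------
  checks <- tools::md5sum(files)
  manifest <- list(schema_version = SCHEMA_VERSION,
                   seed = config$seed,
                   n_shuffles = n_shuffles,
                   stages = stages,
                   files = lapply(seq_along(files), function(i) {
                     list(path = basename(files[i]),
                          md5 = unname(checks[i]))
                   }))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
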