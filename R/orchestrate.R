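#' Default end-to-end run configuration
#'
#' A nested list with one section per stage, every numeric default of the
#' pipeline surfaced. The built-in demo scales are deliberately small so
#' the smoke run finishes in seconds; cohort studies override them.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @return List of class `run_config`.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    psf = list(fwhm_xy = 0.4, fwhm_z = 1.4, n_beads = 24, noise_level = 1),
    cohort = list(
      n_cells = 3,
      pixel_size_xy = 0.16,
      groups = list(
        wt = list(cell_area = 700, n_mitochondria = 25, count_sd = 4,
                  length_mean = 2.34, ratio_mean = 100),
        ko = list(cell_area = 700, n_mitochondria = 40, count_sd = 6,
                  length_mean = 3.32, ratio_mean = 100))),
    pipeline = list(deconv_iterations = 8, min_area = 0.1, max_area = 20,
                    max_branch_points = 0, min_solidity = 0.6,
                    collapse_half_window = 2),
    redox = list(n_cells = 5,
                 groups = list(wt = list(true_oxd = 0.404),
                               ko = list(true_oxd = 0.597)),
                 noise_sd = 0.02)),
    class = "run_config")
}

validate_run_config <- function(config) {
  need <- c("seed", "psf", "cohort", "pipeline", "redox")
  for (f in need) if (is.null(config[[f]]))
    stopf("run config: missing required field '%s'", f)
  for (f in c("fwhm_xy", "fwhm_z", "n_beads"))
    if (is.null(config$psf[[f]]))
      stopf("run config: missing required field 'psf.%s'", f)
  if (is.null(config$cohort$groups) || length(config$cohort$groups) < 1)
    stopf("run config: missing required field 'cohort.groups'")
  for (g in names(config$cohort$groups))
    for (f in c("cell_area", "n_mitochondria"))
      if (is.null(config$cohort$groups[[g]][[f]]))
        stopf("run config: missing required field 'cohort.groups.%s.%s'", g, f)
  for (g in names(config$redox$groups))
    if (is.null(config$redox$groups[[g]]$true_oxd))
      stopf("run config: missing required field 'redox.groups.%s.true_oxd'", g)
  invisible(TRUE)
}

config_fingerprint <- function(config) {
  js <- as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                      digits = NA))
  v <- utf8ToInt(js)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

#' Run the simulated end-to-end pipeline
#'
#' Ties the stages together: bead simulation and PSF estimation, cohort
#' simulation per group, single-particle segmentation, per-cell
#' morphometry, roGFP1 redox quantification, and the group comparisons.
#' Fully deterministic given `config$seed`. Writes `particles.csv`,
#' `cells.csv`, `redox.csv`, `comparisons.csv`, `psf.json` and a
#' `provenance.json` (config fingerprint, seed, package version) into
#' `out_dir`; stages that completed before a failure keep their outputs
#' next to an `error_manifest.json`.
#'
#' @param config A `run_config` list (see [default_run_config()]).
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing and just return the tables.
#' @return List of class `pipeline_run` with elements `psf`, `cells`,
#'   `particles`, `redox`, `comparisons`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  validate_run_config(config)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(out_dir))
      write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }
  fail_manifest <- function(stage, e) {
    if (!is.null(out_dir))
      jsonlite::write_json(list(failed_stage = stage,
                                message = conditionMessage(e)),
                           file.path(out_dir, "error_manifest.json"),
                           auto_unbox = TRUE)
    stopf("pipeline failed in stage '%s': %s", stage, conditionMessage(e))
  }

  # stage 1: PSF characterization
  psf <- tryCatch({
    beads <- generate_bead_stack(config$psf$fwhm_xy, config$psf$fwhm_z,
                                 n_beads = config$psf$n_beads,
                                 noise_level = config$psf$noise_level %||% 1,
                                 seed = derive_seed(config$seed, 1))
    estimate_psf(beads)
  }, error = function(e) fail_manifest("psf", e))
  if (!is.null(out_dir))
    jsonlite::write_json(unclass(psf), file.path(out_dir, "psf.json"),
                         auto_unbox = TRUE, digits = NA)

  # stage 2: cohort simulation + segmentation + morphometry
  pcfg <- do.call(pipeline_config, config$pipeline)
  cells <- list(); parts <- list()
  k <- 0L
  res <- tryCatch({
    for (g in names(config$cohort$groups)) {
      gp <- config$cohort$groups[[g]]
      for (i in seq_len(config$cohort$n_cells)) {
        k <- k + 1L
        set.seed(derive_seed(config$seed, 90000 + k))
        n_mito <- if (is.null(gp$count_sd) || gp$count_sd <= 0)
          gp$n_mitochondria else
          max(0L, round(rtruncnorm_pos(1, gp$n_mitochondria, gp$count_sd)))
        sp <- scene_params(
          cell_area = gp$cell_area, n_mitochondria = n_mito,
          length_mean = gp$length_mean %||% 2.34,
          ratio_mean = gp$ratio_mean %||% 100,
          pixel_size_xy = config$cohort$pixel_size_xy %||% 0.16,
          seed = derive_seed(config$seed, 100 + k))
        scene <- generate_jc1_stack(sp)
        seg <- segment_particles(scene, psf, pcfg)
        cm <- cell_metrics(seg, scene$truth$cell_mask, sp$pixel_size_xy)
        cm$cell_id <- sprintf("%s_%03d", g, i)
        cm$group <- g
        cells[[k]] <- cm
        pr <- seg$records
        if (nrow(pr)) {
          pr$cell_id <- cm$cell_id
          pr$group <- g
          parts[[k]] <- pr
        }
      }
    }
    list(cells = do.call(rbind, cells), particles = do.call(rbind, parts))
  }, error = function(e) fail_manifest("segmentation", e))
  emit(res$cells, "cells.csv")
  emit(res$particles, "particles.csv")

  # stage 3: redox quantification
  redox <- tryCatch({
    rows <- list(); k <- 0L
    for (g in names(config$redox$groups)) {
      oxd <- config$redox$groups[[g]]$true_oxd
      for (i in seq_len(config$redox$n_cells)) {
        k <- k + 1L
        rp <- rogfp_series_params(
          true_oxd = oxd, noise_sd = config$redox$noise_sd %||% 0.02,
          seed = derive_seed(config$seed, 5000 + k))
        rs <- quantify_redox(compute_ratio_trace(generate_rogfp1_series(rp)))
        rows[[k]] <- data.frame(
          cell_id = sprintf("%s_r%03d", g, i), group = g,
          baseline_ratio = rs$baseline_ratio,
          r_red = rs$calibration$r_red, r_ox = rs$calibration$r_ox,
          instrument_factor = rs$calibration$instrument_factor,
          oxd_percent = 100 * rs$oxd, e_mV = rs$e_mV)
      }
    }
    do.call(rbind, rows)
  }, error = function(e) fail_manifest("redox", e))
  emit(redox, "redox.csv")

  # stage 4: group comparisons
  comparisons <- tryCatch({
    gnames <- names(config$cohort$groups)
    cmp_var <- function(df, var, g1, g2) {
      r <- compare_groups(df[[var]][df$group == g1],
                          df[[var]][df$group == g2])
      data.frame(quantity = var, group_a = g1, group_b = g2,
                 mean_a = mean(df[[var]][df$group == g1], na.rm = TRUE),
                 mean_b = mean(df[[var]][df$group == g2], na.rm = TRUE),
                 t = r$t, df = r$df, p = r$p, stars = r$stars)
    }
    if (length(gnames) >= 2) {
      g1 <- gnames[1]; g2 <- gnames[2]
      out <- rbind(
        cmp_var(res$cells, "cell_area_um2", g1, g2),
        cmp_var(res$cells, "total_mito_area_um2", g1, g2),
        cmp_var(res$cells, "particle_count", g1, g2),
        cmp_var(res$cells, "density_count_per_um2", g1, g2),
        cmp_var(res$cells, "mean_particle_length_um", g1, g2),
        cmp_var(res$cells, "mean_particle_ratio", g1, g2),
        cmp_var(redox, "oxd_percent", g1, g2),
        cmp_var(redox, "baseline_ratio", g1, g2))
      out
    } else data.frame()
  }, error = function(e) fail_manifest("compare", e))
  emit(comparisons, "comparisons.csv")

  if (!is.null(out_dir))
    jsonlite::write_json(
      list(seed = config$seed, config_fingerprint = config_fingerprint(config),
           package_version = as.character(utils::packageVersion("mitoquant"))),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE)

  structure(list(psf = psf, cells = res$cells, particles = res$particles,
                 redox = redox, comparisons = comparisons),
            class = "pipeline_run")
}
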