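#' Cohort-level parameter-recovery studies
#'
#' Thin drivers that simulate a cohort of synthetic cells (or roGFP1
#' series), run the full analysis pipeline on each, and return measured
#' versus true quantities. They back both the recovery test suite and the
#' reproducibility report. Cohort geometry is desk-scaled: cells are
#' rendered at 0.16 um/pixel and a few hundred to a few thousand um^2 —
#' smaller than real astrocytes — because the recovered quantities
#' (counts, lengths in um, intensive densities) do not depend on the
#' field of view, while compute grows with its square.
#'
#' @param n_cells Number of cells simulated.
#' @param count_mean,count_sd Per-cell mitochondrion count distribution
#'   (truncated normal, rounded).
#' @param cell_area Cell area per cell (um^2).
#' @param length_mean,length_sd Rod length distribution (um).
#' @param pixel_size_xy Lateral sampling (um/pixel).
#' @param deconv_iterations Richardson-Lucy iterations in the pipeline.
#' @param seed Master seed; each cell derives its own stream.
#' @param psf PSF used for restoration (defaults to the generator truth).
#' @return Data frame with one row per cell: `true_count`,
#'   `retained_count`, `cell_area_um2`, `density_count_per_um2`,
#'   `mean_length_um`, `mean_ratio`.
#' @export
run_count_cohort <- function(n_cells, count_mean, count_sd, cell_area,
                             length_mean = 2.34, length_sd = 0.7,
                             pixel_size_xy = 0.16, deconv_iterations = 8,
                             seed = 1, psf = psf_from_fwhm(0.4, 1.4)) {
  cfg <- pipeline_config(deconv_iterations = deconv_iterations)
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    set.seed(derive_seed(seed, 2L * i))
    n_mito <- max(0L, as.integer(round(
      rtruncnorm_pos(1, count_mean, count_sd))))
    sp <- scene_params(cell_area = cell_area, n_mitochondria = n_mito,
                       length_mean = length_mean, length_sd = length_sd,
                       pixel_size_xy = pixel_size_xy,
                       seed = derive_seed(seed, 2L * i + 1L))
    scene <- generate_jc1_stack(sp)
    seg <- segment_particles(scene, psf, cfg)
    cm <- cell_metrics(seg, scene$truth$cell_mask, pixel_size_xy)
    rows[[i]] <- data.frame(
      true_count = n_mito, retained_count = cm$particle_count,
      cell_area_um2 = cm$cell_area_um2,
      density_count_per_um2 = cm$density_count_per_um2,
      mean_length_um = cm$mean_particle_length_um,
      mean_ratio = cm$mean_particle_ratio)
  }
  do.call(rbind, rows)
}

#' @rdname run_count_cohort
#' @param density_target Target count-based density (per um^2); per-cell
#'   counts are set to `round(density_target * cell_area)`.
#' @export
run_density_cohort <- function(n_cells, density_target, cell_area,
                               length_mean = 2.34, length_sd = 0.7,
                               pixel_size_xy = 0.16, deconv_iterations = 8,
                               seed = 1, psf = psf_from_fwhm(0.4, 1.4)) {
  n0 <- round(density_target * cell_area)
  run_count_cohort(n_cells, count_mean = n0, count_sd = 0,
                   cell_area = cell_area, length_mean = length_mean,
                   length_sd = length_sd, pixel_size_xy = pixel_size_xy,
                   deconv_iterations = deconv_iterations, seed = seed,
                   psf = psf)
}

#' @rdname run_count_cohort
#' @param n_scenes,rods_per_scene Rod-recovery layout: several moderate
#'   fields instead of one huge one.
#' @export
run_length_cohort <- function(n_scenes, rods_per_scene, length_mean,
                              length_sd, cell_area = 600,
                              pixel_size_xy = 0.08, deconv_iterations = 8,
                              seed = 1, psf = psf_from_fwhm(0.4, 1.4)) {
  cfg <- pipeline_config(deconv_iterations = deconv_iterations)
  true_len <- meas_len <- true_ratio <- meas_ratio <- numeric(0)
  for (i in seq_len(n_scenes)) {
    sp <- scene_params(cell_area = cell_area,
                       n_mitochondria = rods_per_scene,
                       length_mean = length_mean, length_sd = length_sd,
                       pixel_size_xy = pixel_size_xy,
                       seed = derive_seed(seed, i))
    scene <- generate_jc1_stack(sp)
    seg <- segment_particles(scene, psf, cfg)
    ret <- seg$records[seg$records$status == "retained", ]
    true_len <- c(true_len, scene$truth$particles$length_um)
    true_ratio <- c(true_ratio, scene$truth$particles$ratio)
    meas_len <- c(meas_len, ret$length_um)
    meas_ratio <- c(meas_ratio, ret$mean_ratio)
  }
  list(true_length = true_len, measured_length = meas_len,
       true_ratio = true_ratio, measured_ratio = meas_ratio)
}

#' @rdname run_count_cohort
#' @param n_series Number of roGFP1 series.
#' @param true_oxd True degree of oxidation for every series.
#' @param noise_sd Per-frame excitation noise SD.
#' @return For `run_redox_cohort`: data frame with `baseline_ratio`,
#'   `oxd`, `r_red`, `r_ox`, `instrument_factor` per series.
#' @export
run_redox_cohort <- function(n_series, true_oxd, noise_sd = 0.02,
                             seed = 1, ...) {
  rows <- vector("list", n_series)
  for (i in seq_len(n_series)) {
    rp <- rogfp_series_params(true_oxd = true_oxd, noise_sd = noise_sd,
                              seed = derive_seed(seed, i), ...)
    rs <- quantify_redox(compute_ratio_trace(generate_rogfp1_series(rp)))
    rows[[i]] <- data.frame(baseline_ratio = rs$baseline_ratio,
                            oxd = rs$oxd,
                            r_red = rs$calibration$r_red,
                            r_ox = rs$calibration$r_ox,
                            instrument_factor =
                              rs$calibration$instrument_factor)
  }
  do.call(rbind, rows)
}
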