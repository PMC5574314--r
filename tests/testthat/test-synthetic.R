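test_that("bead generator renders the requested FWHM and is deterministic", {
  b <- generate_bead_stack(0.4, 1.4, n_beads = 1, noise_level = 0, seed = 1)
  expect_equal(nrow(b$positions), 1)
  # lateral profile through the bead maximum has the requested FWHM
  pr <- extract_bead_profiles(b, window = 1.5)
  fit <- fit_fwhm(average_profiles(pr$x), b$pixel_size_xy)
  expect_lt(abs(fit$fwhm - 0.4), b$pixel_size_xy / 2)

  b2 <- generate_bead_stack(0.4, 1.4, n_beads = 1, noise_level = 0, seed = 1)
  expect_identical(b$stack, b2$stack)
  expect_identical(b$positions, b2$positions)

  b0 <- generate_bead_stack(0.4, 1.4, n_beads = 0, noise_level = 0, seed = 1)
  expect_equal(nrow(b0$positions), 0)
  expect_true(all(b0$stack == b0$stack[1]))

  expect_error(generate_bead_stack(-0.4, 1.4), "positive")
})

test_that("jc1 scene: truth sidecar, pre-blur ratio identity, determinism", {
  sc <- small_scene(seed = 11, n = 10, noise_level = 0)
  expect_equal(nrow(sc$truth$particles), 10)

  # pre-blur channel construction: green * 200 / red equals the true ratio
  # on every rod voxel
  pb <- sc$truth$pre_blur
  on <- pb$red > 0
  ratio_field <- pb$green[on] * 200 / pb$red[on]
  expect_true(all(ratio_field > 0))
  for (i in seq_len(nrow(sc$truth$particles))) {
    p <- sc$truth$particles[i, ]
    cy <- round(p$y_um / sc$params$pixel_size_xy)
    cx <- round(p$x_um / sc$params$pixel_size_xy)
    expect_equal(pb$green[cy, cx] * 200 / pb$red[cy, cx], p$ratio,
                 tolerance = 1e-12)
  }

  sc2 <- small_scene(seed = 11, n = 10, noise_level = 0)
  expect_identical(sc$green, sc2$green)
  expect_identical(sc$red, sc2$red)
  expect_identical(sc$truth$particles, sc2$truth$particles)
})

test_that("jc1 scene truth is self-consistent", {
  sc <- small_scene(seed = 12, n = 30)
  tr <- sc$truth
  expect_equal(sum(tr$particles$area_um2), tr$total_mito_area_um2)
  expect_lte(tr$total_mito_area_um2, tr$cell_area_um2)
  # every rod body voxel lies inside the cell mask: rod centres were drawn
  # from the eroded interior, so check centres plus the pre-blur footprint
  on <- which(tr$pre_blur$red > 0, arr.ind = TRUE)
  expect_true(all(tr$cell_mask[on]))
})

test_that("infeasible scenes error out", {
  expect_error(
    generate_jc1_stack(scene_params(cell_area = 30, n_mitochondria = 40,
                                    pixel_size_xy = 0.16, seed = 1)),
    "infeasible")
  expect_error(scene_params(cell_area = -5), "positive")
  expect_error(scene_params(n_mitochondria = -1), ">= 0")
})

test_that("channel scaling leaves the pre-noise ratio field unchanged", {
  sc <- small_scene(seed = 13, n = 15, noise_level = 0)
  st <- channel_stack(sc$green, sc$red, 0.16)
  st2 <- channel_stack(sc$green * 3.7, sc$red * 3.7, 0.16)
  r1 <- jc1_ratio(st); r2 <- jc1_ratio(st2)
  expect_equal(r1$values, r2$values, tolerance = 1e-12)
})

test_that("shot noise is Poisson-like: variance grows with the mean", {
  set.seed(42)
  flat_lo <- matrix(50, 200, 200)
  flat_hi <- matrix(500, 200, 200)
  v_lo <- var(as.vector(add_shot_noise(flat_lo, 1, read_noise_sd = 0)))
  v_hi <- var(as.vector(add_shot_noise(flat_hi, 1, read_noise_sd = 0)))
  expect_gt(v_hi, 5 * v_lo)
  expect_equal(v_lo, 50, tolerance = 0.15)
  expect_equal(v_hi, 500, tolerance = 0.15)
  expect_identical(add_shot_noise(flat_lo, 0), flat_lo)
})

test_that("mitotracker image: exact truth without noise, linear in signal", {
  sp <- scene_params(cell_area = 400, n_mitochondria = 15,
                     pixel_size_xy = 0.16, noise_level = 0, seed = 21)
  mt <- generate_mitotracker_image(sp, background = 0)
  cell <- mt$truth$cell_mask
  expect_equal(sum(mt$image[cell]), mt$truth$integrated_intensity)

  mt2 <- generate_mitotracker_image(sp, mito_intensity = 1200,
                                    cytosol_intensity = 60, background = 0)
  v1 <- mitotracker_normalized_intensity(mt$image, cell, 0.16)
  v2 <- mitotracker_normalized_intensity(mt2$image, cell, 0.16)
  expect_equal(v2 / v1, 2, tolerance = 1e-10)

  mt3 <- generate_mitotracker_image(sp, background = 0)
  expect_identical(mt$image, mt3$image)
})

test_that("rogfp generator hits the analytic epoch ratios", {
  # true_oxd = 0 -> baseline at r_red; 1 -> r_ox; 0.5 with IF 1 -> midpoint
  for (case in list(list(oxd = 0, expect = 0.5),
                    list(oxd = 1, expect = 2.0),
                    list(oxd = 0.5, expect = 1.25))) {
    p <- rogfp_series_params(true_oxd = case$oxd, r_red = 0.5, r_ox = 2,
                             instrument_factor = 1, noise_sd = 0, seed = 1)
    tr <- compute_ratio_trace(generate_rogfp1_series(p))
    expect_equal(mean(tr$ratios[tr$epochs == "baseline"]), case$expect,
                 tolerance = 1e-10)
    expect_equal(mean(tr$ratios[tr$epochs == "oxidant"]), 2, tolerance = 1e-10)
    expect_equal(mean(tr$ratios[tr$epochs == "reductant"]), 0.5,
                 tolerance = 1e-10)
  }
  expect_error(rogfp_series_params(true_oxd = 0.5, r_red = 2, r_ox = 1),
               "r_red")
  expect_error(rogfp_series_params(true_oxd = 1.4), "\\[0, 1\\]")
})
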