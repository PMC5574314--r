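test_that("cell area is pixel count times pixel area", {
  m <- matrix(FALSE, 120, 120)
  m[11:110, 11:110] <- TRUE                  # 100 x 100 px at 0.08 um/px
  expect_equal(cell_area(m, 0.08), 64)

  expect_error(cell_area(matrix(FALSE, 5, 5), 0.08), "empty")

  disc <- matrix(FALSE, 20, 20)
  disc[2:4, 2:4] <- TRUE; disc[15:17, 15:17] <- TRUE
  expect_error(cell_area(disc, 0.08), "connected")
})

test_that("mitochondrial mass sums all above-threshold pixels", {
  m <- matrix(FALSE, 50, 50)
  m[seq_len(1000)] <- TRUE
  expect_equal(as.numeric(total_mito_mass(m, 0.08)), 6.4)
  expect_equal(attr(total_mito_mass(m, 0.08, z_step = 0.25), "volume_um3"),
               1.6)
  expect_equal(as.numeric(total_mito_mass(matrix(FALSE, 5, 5), 0.08)), 0)
})

test_that("density is a plain quotient in both variants", {
  expect_equal(mito_density(10, 100), 0.1)       # count-based, per um^2
  expect_equal(mito_density(64, 640), 0.1)       # area fraction
  expect_equal(mito_density(0, 640), 0)
  expect_error(mito_density(10, 0), "> 0")
})

test_that("per-cell identity holds exactly on pipeline output", {
  sc <- small_scene(seed = 51, n = 25)
  seg <- segment_particles(sc, psf_truth, fast_config())
  cm <- cell_metrics(seg, sc$truth$cell_mask, 0.16)
  expect_equal(cm$density_count_per_um2 * cm$cell_area_um2,
               cm$particle_count, tolerance = 1e-12)
  expect_lte(cm$total_mito_area_um2, cm$cell_area_um2)
  expect_equal(cm$cell_area_um2, sc$truth$cell_area_um2)
})

test_that("mitotracker normalization: linearity, zero cell, degenerate masks", {
  img <- matrix(0, 40, 40)
  cellm <- matrix(FALSE, 40, 40)
  cellm[10:30, 10:30] <- TRUE
  img[cellm] <- 50
  v <- mitotracker_normalized_intensity(img, cellm, 0.08)
  img2 <- img; img2[cellm] <- 100
  expect_equal(mitotracker_normalized_intensity(img2, cellm, 0.08), 2 * v)

  expect_equal(mitotracker_normalized_intensity(matrix(0, 40, 40), cellm,
                                                0.08), 0)
  expect_error(mitotracker_normalized_intensity(img, matrix(TRUE, 40, 40),
                                                0.08), "background")
  expect_error(mitotracker_normalized_intensity(img, matrix(FALSE, 40, 40),
                                                0.08), "empty")
})

test_that("mitotracker output tracks generator truth across seeds", {
  outs <- truths <- numeric(0)
  for (s in 61:66) {
    sp <- scene_params(cell_area = 400, n_mitochondria = 8 + 4 * (s %% 3),
                       pixel_size_xy = 0.16, noise_level = 1, seed = s)
    mt <- generate_mitotracker_image(sp)
    outs <- c(outs, mitotracker_normalized_intensity(
      mt$image, mt$truth$cell_mask, 0.16))
    bg_term <- mt$truth$background * sum(mt$truth$cell_mask)
    truths <- c(truths, (mt$truth$integrated_intensity - bg_term) /
                  (sum(mt$truth$cell_mask) * 0.16^2))
  }
  expect_gt(cor(outs, truths), 0.99)
  expect_equal(mean(outs / truths), 1, tolerance = 0.05)
})

test_that("genotype-style cohorts reproduce the expected directions", {
  # scaled-down two-group cohort: the null-like group has more rods in the
  # same cell area; direction of count, mass, density must follow, cell
  # area must not differ meaningfully
  wt <- run_count_cohort(4, count_mean = 20, count_sd = 2, cell_area = 600,
                         seed = 71)
  ko <- run_count_cohort(4, count_mean = 32, count_sd = 3, cell_area = 600,
                         seed = 72)
  expect_gt(mean(ko$retained_count), mean(wt$retained_count))
  expect_gt(mean(ko$density_count_per_um2), mean(wt$density_count_per_um2))
  expect_equal(mean(ko$cell_area_um2) / mean(wt$cell_area_um2), 1,
               tolerance = 0.05)
})
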