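test_that("config validation fails before any computation, naming the field", {
  cfg <- default_run_config(seed = 1)
  cfg$psf$fwhm_xy <- NULL
  expect_error(run_pipeline(cfg), "psf.fwhm_xy")
  cfg2 <- default_run_config(seed = 1)
  cfg2$redox$groups$wt$true_oxd <- NULL
  expect_error(run_pipeline(cfg2), "redox.groups.wt.true_oxd")
})

test_that("end-to-end demo run produces all tables deterministically", {
  cfg <- default_run_config(seed = 3)
  cfg$cohort$n_cells <- 2
  cfg$redox$n_cells <- 3
  out <- file.path(tempdir(), "mitoquant-demo")
  run <- run_pipeline(cfg, out_dir = out)
  expect_true(all(file.exists(file.path(
    out, c("particles.csv", "cells.csv", "redox.csv", "comparisons.csv",
           "psf.json", "provenance.json")))))
  expect_gt(nrow(run$particles), 0)
  expect_equal(nrow(run$cells), 4)
  expect_equal(nrow(run$redox), 6)
  expect_true(all(c("quantity", "p", "stars") %in% names(run$comparisons)))

  run2 <- run_pipeline(cfg, out_dir = NULL)
  expect_identical(run$cells, run2$cells)
  expect_identical(run$particles, run2$particles)
  expect_identical(run$redox, run2$redox)
  unlink(out, recursive = TRUE)
})

test_that("text stack format round-trips images and truth sidecars", {
  sc <- small_scene(seed = 81, n = 5)
  f <- tempfile(fileext = ".stack.txt")
  write_stack_txt(list(green = sc$green, red = sc$red), f,
                  pixel_size_xy = 0.16, z_step = 0.25)
  back <- read_stack_txt(f)
  expect_equal(back$green, sc$green, tolerance = 1e-12)
  expect_equal(back$red, sc$red, tolerance = 1e-12)
  expect_equal(attr(back, "pixel_size_xy"), 0.16)

  pre <- tempfile()
  paths <- write_truth_sidecar(sc, pre)
  expect_true(all(file.exists(paste0(pre, c("_particles.csv",
                                            "_params.json")))))
  tr <- read.csv(paste0(pre, "_particles.csv"))
  expect_equal(nrow(tr), 5)
  unlink(c(f, paths))
})
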