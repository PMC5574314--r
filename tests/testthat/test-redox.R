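test_that("ratio trace: identity, linearity, shape checks", {
  f <- array(50, dim = c(6, 6, 10))
  mask <- matrix(TRUE, 6, 6)
  tr <- compute_ratio_trace(f, f, mask)
  expect_equal(tr$ratios, rep(1, 10))

  tr2 <- compute_ratio_trace(2 * f, f, mask)
  expect_equal(tr2$ratios, rep(2, 10))

  expect_error(compute_ratio_trace(f, f[, , 1:9], mask), "shape|length")
  expect_error(compute_ratio_trace(f, f, matrix(FALSE, 6, 6)), "empty")

  fz <- f; fz[, , 4] <- 0
  expect_warning(tr3 <- compute_ratio_trace(f, fz, mask), "invalid")
  expect_true(is.na(tr3$ratios[4]))
})

test_that("calibration round-trips the generator exactly without noise", {
  p <- rogfp_series_params(true_oxd = 0.404, noise_sd = 0, seed = 1)
  cal <- extract_calibration(compute_ratio_trace(generate_rogfp1_series(p)))
  expect_equal(cal$r_red, 0.5, tolerance = 1e-10)
  expect_equal(cal$r_ox, 2.0, tolerance = 1e-10)
  expect_equal(cal$instrument_factor, 0.5737, tolerance = 1e-10)
})

test_that("calibration fails informatively on missing epochs", {
  p <- rogfp_series_params(true_oxd = 0.3, noise_sd = 0, seed = 1)
  s <- generate_rogfp1_series(p)
  tr <- compute_ratio_trace(s)
  tr$epochs[tr$epochs == "reductant"] <- "baseline"
  expect_error(extract_calibration(tr), "reductant")
  tr2 <- compute_ratio_trace(s)
  tr2$epochs <- NULL
  expect_error(extract_calibration(tr2), "unlabeled")
})

test_that("noisy calibration estimates stay within 3 SE of truth", {
  vals <- t(vapply(1:25, function(s) {
    p <- rogfp_series_params(true_oxd = 0.4, noise_sd = 0.02, seed = s)
    cal <- extract_calibration(compute_ratio_trace(generate_rogfp1_series(p)))
    c(cal$r_red, cal$r_ox, cal$instrument_factor)
  }, numeric(3)))
  truth <- c(0.5, 2.0, 0.5737)
  for (j in 1:3) {
    se <- sd(vals[, j]) / sqrt(nrow(vals))
    expect_lt(abs(mean(vals[, j]) - truth[j]), 3 * se + 1e-6)
  }
})

test_that("OxD endpoints, midpoint and monotonicity", {
  cal <- structure(list(r_red = 0.5, r_ox = 2, instrument_factor = 1),
                   class = "calibration_result")
  expect_equal(as.numeric(compute_oxd(0.5, cal)), 0)
  expect_equal(as.numeric(compute_oxd(2.0, cal)), 1)
  expect_equal(as.numeric(compute_oxd(1.25, cal)), 0.5)

  for (IF in c(0.3, 0.5737, 1, 2.5)) {
    cal2 <- structure(list(r_red = 0.5, r_ox = 2, instrument_factor = IF),
                      class = "calibration_result")
    R <- seq(0.51, 1.99, length.out = 60)
    oxd <- as.numeric(compute_oxd(R, cal2))
    expect_true(all(diff(oxd) > 0))
  }

  out <- compute_oxd(2.4, cal)
  expect_equal(as.numeric(out), 1)
  expect_true(attr(out, "clamped"))

  bad <- structure(list(r_red = 1, r_ox = 1, instrument_factor = 1),
                   class = "calibration_result")
  expect_error(compute_oxd(1, bad), "degenerate")
})

test_that("Nernst potential: midpoint identity, oracle value, symmetry", {
  expect_equal(compute_potential(0.5, e0_mV = -291), -291)

  # independent evaluation of E = e0 - (RT/2F) ln((1-oxd)/oxd)
  oracle <- -291 - 1000 * (8.314462618 * 298.15 / (2 * 96485.33212)) *
    log((1 - 0.731) / 0.731)
  expect_equal(compute_potential(0.731, -291, 298.15), oracle)
  expect_equal(oracle, -278.2, tolerance = 0.05)

  expect_error(compute_potential(0), "endpoints")
  expect_error(compute_potential(1), "endpoints")

  # strictly increasing in oxd, antisymmetric about 0.5
  ox <- seq(0.05, 0.95, by = 0.05)
  e <- compute_potential(ox, -291, 310.15)
  expect_true(all(diff(e) > 0))
  expect_equal(e - (-291), -rev(e - (-291)), tolerance = 1e-9)
})

test_that("end-to-end OxD recovery within 0.02 absolute under noise", {
  for (oxd_true in c(0.2, 0.404, 0.5, 0.597, 0.8)) {
    res <- run_redox_cohort(20, oxd_true, noise_sd = 0.02,
                            seed = round(1000 * oxd_true))
    expect_lt(abs(mean(res$oxd) - oxd_true), 0.02)
  }
})
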