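test_that("fit_fwhm matches the closed form on exact Gaussians", {
  # sigma = 1 px, pixel 1 um -> FWHM = 2 sqrt(2 ln 2) = 2.3548
  p <- gauss_profile(21, 11, 1)
  fit <- fit_fwhm(p, 1)
  expect_equal(fit$fwhm, 2 * sqrt(2 * log(2)), tolerance = 1e-6)

  # sigma = 0.1699 um: independent evaluation of 2 sqrt(2 ln 2) * sigma
  sigma_um <- 0.1699
  px <- 0.08
  p2 <- gauss_profile(31, 16, sigma_um / px)
  fit2 <- fit_fwhm(p2, px)
  expect_equal(fit2$fwhm, 2 * sqrt(2 * log(2)) * sigma_um, tolerance = 1e-6)
  expect_equal(fit2$fwhm, 0.40, tolerance = 0.01)

  expect_error(fit_fwhm(rep(7, 31), 1), "flat")
})

test_that("fitted FWHM is within 1% of analytic for a range of widths", {
  for (s in c(1, 1.7, 3, 5.5)) {
    p <- gauss_profile(ceiling(12 * s) * 2 + 1, ceiling(12 * s) + 1, s)
    fit <- fit_fwhm(p, 0.25)
    expect_equal(fit$fwhm, sigma_to_fwhm(s) * 0.25,
                 tolerance = 0.01)
  }
})

test_that("profile extraction: symmetry, border handling, empty input", {
  b <- generate_bead_stack(0.4, 1.4, n_beads = 1, noise_level = 0, seed = 5,
                           subpixel_jitter = 0)
  pr <- extract_bead_profiles(b, window = 1.2)
  prof <- pr$x[[1]]
  m <- which.max(prof)
  k <- min(m - 1, length(prof) - m)
  expect_equal(prof[(m - k):(m - 1)], rev(prof[(m + 1):(m + k)]),
               tolerance = 1e-8)

  # a bead pushed against the border is skipped and the count decremented
  b2 <- b
  b2$positions <- rbind(b2$positions,
                        data.frame(y_um = 0.08, x_um = 0.08, z_um = 0.25))
  expect_warning(pr2 <- extract_bead_profiles(b2, window = 1.2), "border")
  expect_equal(pr2$n_beads_used, 1)

  b3 <- b
  b3$positions <- b3$positions[0, ]
  expect_error(extract_bead_profiles(b3), "empty|no bead")
})

test_that("profile averaging is exact on identical and offset inputs", {
  p <- gauss_profile(21, 11, 2)
  expect_equal(average_profiles(rep(list(p), 24)), p)

  # symmetric perturbations around a mean cancel
  d <- c(rep(0, 10), 3, rep(0, 10))
  expect_equal(average_profiles(list(p + d, p - d)), p)

  expect_error(average_profiles(list()), "empty")
  expect_error(average_profiles(list(p, p[-1])), "length")
})

test_that("end-to-end PSF recovery on noisy 24-bead stacks is within 10%", {
  b <- generate_bead_stack(0.4, 1.4, n_beads = 24, noise_level = 1, seed = 2)
  est <- estimate_psf(b)
  expect_equal(est$n_beads_used, 24)
  expect_lt(abs(est$fwhm_xy - 0.4) / 0.4, 0.10)
  expect_lt(abs(est$fwhm_z - 1.4) / 1.4, 0.10)
  expect_equal(est$fwhm_xy, sigma_to_fwhm(est$sigma_xy))
})

test_that("averaging more beads reduces estimator spread", {
  est_n <- function(n, seed) {
    b <- generate_bead_stack(0.4, 1.4, n_beads = n, noise_level = 4,
                             seed = seed)
    estimate_psf(b)$fwhm_xy
  }
  few <- vapply(1:8, function(s) est_n(2, s), 1)
  many <- vapply(1:8, function(s) est_n(16, s), 1)
  expect_lt(sd(many), sd(few))
})
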