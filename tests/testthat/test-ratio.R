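test_that("ratio arithmetic follows the scaled emission-ratio definition", {
  g <- array(c(100, 0, 50, 30), dim = c(2, 2, 1))
  r <- array(c(100, 80, 100, 60), dim = c(2, 2, 1))
  out <- jc1_ratio(channel_stack(g, r))
  expect_equal(out$values[1, 1, 1], 200)   # equal channels -> 200 exactly
  expect_equal(out$values[2, 1, 1], 0)     # zero green -> 0
  expect_equal(out$values[1, 2, 1], 100)   # 50 * 200 / 100
  expect_equal(out$values[2, 2, 1], 100)

  # equal channels give 200 at every voxel
  gg <- array(runif(4 * 4 * 3, 1, 500), dim = c(4, 4, 3))
  out2 <- jc1_ratio(channel_stack(gg, gg))
  expect_true(all(out2$values == 200))
})

test_that("zero-red voxels are flagged invalid, not clamped", {
  g <- matrix(c(10, 20, 30, 40), 2, 2)
  r <- matrix(c(5, 0, 10, 0), 2, 2)
  out <- jc1_ratio(channel_stack(g, r))
  expect_identical(out$invalid, r == 0)
  expect_true(all(is.na(out$values[r == 0])))
  expect_true(all(!is.na(out$values[r > 0])))
})

test_that("ratio is scale-invariant and monotone in each channel", {
  set.seed(1)
  g <- matrix(runif(100, 1, 200), 10, 10)
  r <- matrix(runif(100, 1, 200), 10, 10)
  base <- jc1_ratio(channel_stack(g, r))$values
  for (c_fac in c(0.5, 3, 17)) {
    expect_equal(jc1_ratio(channel_stack(g * c_fac, r * c_fac))$values,
                 base, tolerance = 1e-12)
  }
  up_g <- jc1_ratio(channel_stack(g * 1.3, r))$values
  up_r <- jc1_ratio(channel_stack(g, r * 1.3))$values
  expect_true(all(up_g > base))
  expect_true(all(up_r < base))
})

test_that("shape mismatch and invalid scaling are rejected", {
  g <- matrix(1, 4, 4)
  expect_error(channel_stack(g, matrix(1, 4, 5)), "dimensions")
  expect_error(jc1_ratio(channel_stack(g, g), scaling = 0), "scaling")
  expect_error(channel_stack(g - 2, g), ">= 0")
})
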