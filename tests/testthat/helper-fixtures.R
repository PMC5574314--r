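# Shared fixtures: everything is generated in code, nothing on disk.

psf_truth <- psf_from_fwhm(0.4, 1.4)

# Small, fast scene used across pipeline tests (0.16 um px keeps the
# field ~290 px wide).
small_scene <- function(seed = 3, n = 40, noise_level = 1, decoys = FALSE,
                        ...) {
  generate_jc1_stack(scene_params(cell_area = 700, n_mitochondria = n,
                                  pixel_size_xy = 0.16,
                                  noise_level = noise_level,
                                  decoys = decoys, seed = seed, ...))
}

fast_config <- function(...) pipeline_config(deconv_iterations = 8, ...)

# Analytic 1-D Gaussian profile on an integer grid.
gauss_profile <- function(n, mu, sigma, a = 100, b = 5) {
  b + a * exp(-((seq_len(n) - mu)^2) / (2 * sigma^2))
}
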