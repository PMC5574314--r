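#' Convert between Gaussian sigma and FWHM
#'
#' For a Gaussian profile the full width at half maximum is
#' `2 * sqrt(2 * log(2)) * sigma` (about 2.3548 sigma).
#'
#' @param sigma,fwhm Numeric values (any unit; the conversion is linear).
#' @return The converted value in the same unit.
#' @export
sigma_to_fwhm <- function(sigma) 2 * sqrt(2 * log(2)) * sigma

#' @rdname sigma_to_fwhm
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Odd-length unit-sum 1-D Gaussian kernel, truncated at 4 sigma.
gauss_kernel <- function(sigma_px) {
  if (sigma_px <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma_px))
  x <- (-h):h
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Separable Gaussian blur of a 2-D matrix or 3-D array [y, x, z].
# sigma_px: length 2 (y, x) or 3 (y, x, z) in pixels; zero skips the axis.
blur_gaussian <- function(arr, sigma_px) {
  d <- dim(arr)
  if (is.null(d)) stopf("blur_gaussian() needs a matrix or array")
  was_mat <- length(d) == 2L
  if (was_mat) {
    dim(arr) <- c(d, 1L)
    sigma_px <- c(sigma_px[1:2], 0)
  }
  for (ax in 0:2) {
    s <- sigma_px[ax + 1]
    if (is.na(s) || s <= 0) next
    arr <- .conv_axis(arr, gauss_kernel(s), ax)
  }
  if (was_mat) dim(arr) <- d
  arr
}

# Truncated-normal sampler (lower bound 0, strictly positive draws) by
# rejection; adequate for the mild truncation used here.
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, draw[draw > 0])
  }
  out[seq_len(n)]
}

# Shot-noise model: Poisson counts at a configurable photon scale plus
# Gaussian read noise, clamped at zero. noise_level = variance multiplier at
# fixed mean (1 = ideal Poisson); 0 disables noise entirely.
add_shot_noise <- function(arr, noise_level, read_noise_sd = 2) {
  if (noise_level <= 0) return(arr)
  d <- dim(arr)
  lam <- pmax(arr, 0) / noise_level
  out <- rpois(length(lam), lam) * noise_level +
    rnorm(length(lam), 0, read_noise_sd)
  out <- pmax(out, 0)
  dim(out) <- d
  out
}

# Stable child seeds for multi-part simulations driven by one user seed.
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1009L + as.integer(k) %% 1009L
}
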