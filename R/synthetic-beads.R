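#' Generate a synthetic sub-resolution bead stack
#'
#' Renders point-like (100 nm) fluorescent beads as 3-D Gaussians whose
#' lateral and axial FWHM equal the requested values before noise — i.e.
#' the beads directly carry the point spread function to be estimated.
#' Beads are laid out on a jittered grid with spacing of at least five
#' lateral FWHM so neighbouring profiles do not overlap, with sub-pixel
#' positions.
#'
#' @param fwhm_xy,fwhm_z Lateral and axial FWHM of the rendered PSF (um).
#' @param n_beads Number of beads to place (0 gives a background-only
#'   stack).
#' @param noise_level Shot-noise scale passed to [add_shot_noise()];
#'   0 = noise-free.
#' @param seed Integer seed for reproducible placement and noise.
#' @param pixel_size_xy Lateral sampling (um/pixel), default 0.08.
#' @param z_step Axial sampling (um/plane), default 0.25.
#' @param amplitude Peak bead intensity above background.
#' @param background Constant background level.
#' @param subpixel_jitter Half-range (pixels) of the uniform sub-pixel
#'   offset applied to each bead centre; 0 pins beads to pixel centres.
#' @return List of class `bead_stack`: `stack` (3-D array `[y, x, z]`),
#'   `positions` (data frame of true bead centres in um), `pixel_size_xy`,
#'   `z_step`.
#' @export
generate_bead_stack <- function(fwhm_xy, fwhm_z, n_beads = 24,
                                noise_level = 0, seed = NULL,
                                pixel_size_xy = 0.08, z_step = 0.25,
                                amplitude = 1000, background = 10,
                                subpixel_jitter = 0.5) {
  if (fwhm_xy <= 0 || fwhm_z <= 0) stopf("FWHM values must be positive")
  if (n_beads < 0) stopf("n_beads must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  sx <- fwhm_to_sigma(fwhm_xy) / pixel_size_xy   # px
  sz <- fwhm_to_sigma(fwhm_z) / z_step           # planes
  spacing <- 5 * fwhm_xy / pixel_size_xy         # px between grid nodes
  ngrid <- ceiling(sqrt(max(n_beads, 1)))
  border <- ceiling(spacing / 2) + ceiling(4 * sx)
  side <- ceiling(ngrid * spacing) + 2 * border
  nz <- 2L * (ceiling(4 * sz) + ceiling(2.5 * fwhm_z / z_step)) + 1L
  zc <- (nz + 1) / 2
  stack <- array(background, dim = c(side, side, nz))
  pos <- data.frame(y_um = numeric(0), x_um = numeric(0), z_um = numeric(0))
  if (n_beads > 0) {
    cells <- sample(ngrid * ngrid, n_beads)
    for (b in seq_len(n_beads)) {
      gy <- (cells[b] - 1) %% ngrid
      gx <- (cells[b] - 1) %/% ngrid
      j <- subpixel_jitter
      cy <- round(border + (gy + 0.5) * spacing) + runif(1, -j, j)
      cx <- round(border + (gx + 0.5) * spacing) + runif(1, -j, j)
      cz <- zc + runif(1, -j, j)
      wy <- max(1, floor(cy - 4 * sx)):min(side, ceiling(cy + 4 * sx))
      wx <- max(1, floor(cx - 4 * sx)):min(side, ceiling(cx + 4 * sx))
      wz <- max(1, floor(cz - 4 * sz)):min(nz, ceiling(cz + 4 * sz))
      gy1 <- exp(-(wy - cy)^2 / (2 * sx^2))
      gx1 <- exp(-(wx - cx)^2 / (2 * sx^2))
      gz1 <- exp(-(wz - cz)^2 / (2 * sz^2))
      bead <- amplitude * outer(outer(gy1, gx1), gz1)
      stack[wy, wx, wz] <- stack[wy, wx, wz] + bead
      pos <- rbind(pos, data.frame(y_um = cy * pixel_size_xy,
                                   x_um = cx * pixel_size_xy,
                                   z_um = cz * z_step))
    }
  }
  if (noise_level > 0) stack <- add_shot_noise(stack, noise_level)
  structure(list(stack = stack, positions = pos,
                 pixel_size_xy = pixel_size_xy, z_step = z_step),
            class = "bead_stack")
}
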