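#' Parameters for a synthetic astrocyte scene
#'
#' Describes one simulated, flatly grown cultured astrocyte containing
#' rod-shaped mitochondria, imaged as a registered dual-emission 3-D stack.
#' Defaults follow the acquisition geometry of the emission-ratiometric
#' two-photon setup being emulated: 80 nm lateral pixels, 0.25 um axial
#' steps, a lateral resolution of 0.4 um and an axial resolution of 1.4 um.
#'
#' Mitochondria are rendered as capsules (straight segment with
#' hemispherical caps) of fixed diameter `rod_diameter` (default 0.4 um,
#' a typical mitochondrial width). Per-particle length and JC-1 ratio are
#' drawn from normal distributions truncated at zero. The per-particle
#' polarization enters the two emission channels so that, before blurring
#' and noise, `green * ratio_scaling / red` equals the particle's true
#' ratio at every voxel.
#'
#' @param cell_area Target cell area in um^2.
#' @param n_mitochondria Number of rods to place (a fixed count; cohort
#'   level dispersion is applied by the caller).
#' @param length_mean,length_sd Tip-to-tip rod length distribution (um).
#' @param ratio_mean,ratio_sd Per-particle JC-1 ratio distribution on the
#'   x200 emission-ratio scale.
#' @param pixel_size_xy Lateral sampling (um/pixel).
#' @param z_step Axial sampling (um/plane).
#' @param n_planes Number of axial planes in the stack (odd; rods sit in
#'   the central plane of a thin, flat cell).
#' @param psf_fwhm_xy,psf_fwhm_z Gaussian PSF FWHM (um) applied to the
#'   rendered scene.
#' @param rod_diameter Mitochondrial width (um).
#' @param red_intensity Red-channel amplitude of a rod before blurring
#'   (arbitrary photon-scaled units).
#' @param noise_level Shot-noise scale; 0 disables noise (see
#'   [add_shot_noise()]).
#' @param read_noise_sd Gaussian read-noise SD added after the Poisson
#'   stage.
#' @param margin Minimum clearance (um) kept between rods and between a rod
#'   and the cell edge, so ground-truth particles are non-overlapping and
#'   interior.
#' @param decoys If `TRUE`, inject objects that the spatial filter must
#'   reject: a border-touching rod, a fused (overlapping) rod pair, a single
#'   bright pixel, and an oversized aggregate.
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(cell_area = 1500, n_mitochondria = 50,
                         length_mean = 2.34, length_sd = 0.7,
                         ratio_mean = 100, ratio_sd = 30,
                         pixel_size_xy = 0.08, z_step = 0.25,
                         n_planes = 7,
                         psf_fwhm_xy = 0.4, psf_fwhm_z = 1.4,
                         rod_diameter = 0.4, red_intensity = 800,
                         noise_level = 1, read_noise_sd = 2,
                         margin = 0.25, decoys = FALSE, seed = NULL) {
  p <- list(cell_area = cell_area, n_mitochondria = n_mitochondria,
            length_mean = length_mean, length_sd = length_sd,
            ratio_mean = ratio_mean, ratio_sd = ratio_sd,
            pixel_size_xy = pixel_size_xy, z_step = z_step,
            n_planes = as.integer(n_planes),
            psf_fwhm_xy = psf_fwhm_xy, psf_fwhm_z = psf_fwhm_z,
            rod_diameter = rod_diameter, red_intensity = red_intensity,
            noise_level = noise_level, read_noise_sd = read_noise_sd,
            margin = margin, decoys = isTRUE(decoys), seed = seed)
  pos <- c("cell_area", "length_mean", "ratio_mean", "pixel_size_xy",
           "z_step", "psf_fwhm_xy", "psf_fwhm_z", "rod_diameter",
           "red_intensity")
  for (f in pos) if (!is.numeric(p[[f]]) || p[[f]] <= 0)
    stopf("scene_params: '%s' must be strictly positive", f)
  for (f in c("length_sd", "ratio_sd", "noise_level", "read_noise_sd",
              "margin"))
    if (p[[f]] < 0) stopf("scene_params: '%s' must be >= 0", f)
  if (p$n_mitochondria < 0) stopf("scene_params: n_mitochondria must be >= 0")
  if (p$n_planes < 1) stopf("scene_params: n_planes must be >= 1")
  structure(p, class = "scene_params")
}

# Smoothed random blob of (approximately) the requested pixel area, built
# from a low-order radial Fourier outline; emulates a flatly grown
# astrocyte. Returns a logical matrix.
make_cell_mask <- function(area_px, ny, nx) {
  amp <- abs(rnorm(4, 0, 0.08 / (1:4)))
  phs <- runif(4, 0, 2 * pi)
  # analytic polygon area of r(theta) = r0 (1 + sum a_k cos(k theta + p_k))
  r0 <- sqrt(area_px / (pi * (1 + sum(amp^2) / 2)))
  cy <- ny / 2; cx <- nx / 2
  yy <- matrix(seq_len(ny) - cy, ny, nx)
  xx <- matrix(seq_len(nx) - cx, ny, nx, byrow = TRUE)
  th <- atan2(yy, xx)
  r <- r0 * (1 + amp[1] * cos(2 * th + phs[1]) + amp[2] * cos(3 * th + phs[2]) +
               amp[3] * cos(4 * th + phs[3]) + amp[4] * cos(5 * th + phs[4]))
  sqrt(yy^2 + xx^2) <= r
}

# Pixel indices (2-column matrix, y/x) of a capsule: all pixels within
# `radius_px` of the segment of half-length `hl_px` centred at (cy, cx)
# with orientation theta. Tip-to-tip length = 2 * hl_px + 2 * radius_px.
capsule_pixels <- function(cy, cx, theta, hl_px, radius_px, ny, nx) {
  ux <- cos(theta); uy <- sin(theta)
  ext <- hl_px + radius_px + 1
  y0 <- max(1L, floor(cy - ext)); y1 <- min(ny, ceiling(cy + ext))
  x0 <- max(1L, floor(cx - ext)); x1 <- min(nx, ceiling(cx + ext))
  if (y0 > y1 || x0 > x1) return(cbind(y = integer(0), x = integer(0)))
  ys <- y0:y1; xs <- x0:x1
  yy <- matrix(ys, length(ys), length(xs))
  xx <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  dy <- yy - cy; dx <- xx - cx
  t <- pmin(pmax(dx * ux + dy * uy, -hl_px), hl_px)
  d2 <- (dx - t * ux)^2 + (dy - t * uy)^2
  keep <- d2 <= radius_px^2
  cbind(y = yy[keep], x = xx[keep])
}

#' Generate a ground-truthed dual-emission JC-1 stack
#'
#' Renders a synthetic astrocyte with non-overlapping interior
#' mitochondrial rods, each carrying its own membrane-potential readout
#' (JC-1 green/red emission ratio), then applies a separable Gaussian PSF
#' and Poisson-plus-read noise. The returned truth sidecar lists every
#' particle with its true length and ratio, enabling parameter-recovery
#' tests of the whole downstream pipeline.
#'
#' @param params A [scene_params()] object.
#' @return A list of class `jc1_scene` with elements `green`, `red`
#'   (3-D arrays `[y, x, z]`), `truth` (list: `cell_mask`, `particles`
#'   data frame, `decoys`, `cell_area_um2`, `total_mito_area_um2`) and
#'   `params`.
#' @export
generate_jc1_stack <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  px <- p$pixel_size_xy
  area_px <- p$cell_area / px^2
  # bounding box: blob radius * safety + border padding
  r_max <- sqrt(area_px / pi) * 1.45
  pad <- ceiling(2 * fwhm_to_sigma(p$psf_fwhm_xy) / px) + 4L
  n_side <- 2L * ceiling(r_max) + 2L * pad
  ny <- nx <- n_side
  cell <- make_cell_mask(area_px, ny, nx)

  radius_px <- p$rod_diameter / 2 / px
  margin_px <- p$margin / px
  interior <- .erode(cell, as.integer(ceiling(radius_px + margin_px)))
  int_idx <- which(interior)
  if (p$n_mitochondria > 0 && length(int_idx) == 0)
    stopf("infeasible scene: cell interior empty after margin erosion")

  # quick feasibility check: requested mitochondrial footprint vs cell area
  mean_rod_area <- p$length_mean * p$rod_diameter
  if (p$n_mitochondria * mean_rod_area > 0.55 * p$cell_area)
    stopf("infeasible scene: requested mitochondrial area (%.0f um^2) %s",
          p$n_mitochondria * mean_rod_area,
          sprintf("exceeds the placeable fraction of the %.0f um^2 cell",
                  p$cell_area))

  occ <- matrix(FALSE, ny, nx)   # margin-dilated occupancy of placed rods
  red2d <- matrix(0, ny, nx)
  green2d <- matrix(0, ny, nx)
  lengths <- if (p$n_mitochondria > 0)
    rtruncnorm_pos(p$n_mitochondria, p$length_mean, p$length_sd) else numeric(0)
  ratios <- if (p$n_mitochondria > 0)
    rtruncnorm_pos(p$n_mitochondria, p$ratio_mean, p$ratio_sd) else numeric(0)

  parts <- vector("list", p$n_mitochondria)
  for (i in seq_len(p$n_mitochondria)) {
    L_px <- lengths[i] / px
    hl <- max(L_px / 2 - radius_px, 0.5)
    placed <- FALSE
    for (try in 1:1000) {
      ctr <- int_idx[sample.int(length(int_idx), 1L)]
      cy <- (ctr - 1L) %% ny + 1L
      cx <- (ctr - 1L) %/% ny + 1L
      theta <- runif(1, 0, pi)
      guard <- capsule_pixels(cy, cx, theta, hl, radius_px + margin_px, ny, nx)
      if (nrow(guard) == 0) next
      ok <- all(interior[guard]) && !any(occ[guard])
      if (!ok) next
      body <- capsule_pixels(cy, cx, theta, hl, radius_px, ny, nx)
      occ[guard] <- TRUE
      red2d[body] <- p$red_intensity
      green2d[body] <- ratios[i] * p$red_intensity / 200
      parts[[i]] <- data.frame(
        id = i, y_um = cy * px, x_um = cx * px, theta = theta,
        length_um = lengths[i], ratio = ratios[i],
        area_um2 = nrow(body) * px^2)
      placed <- TRUE
      break
    }
    if (!placed)
      stopf("infeasible scene: could not place rod %d of %d without overlap",
            i, p$n_mitochondria)
  }
  particles <- if (p$n_mitochondria > 0) do.call(rbind, parts) else
    data.frame(id = integer(0), y_um = numeric(0), x_um = numeric(0),
               theta = numeric(0), length_um = numeric(0), ratio = numeric(0),
               area_um2 = numeric(0))

  decoys <- data.frame(kind = character(0), y_px = numeric(0),
                       x_px = numeric(0))
  if (p$decoys) {
    rr <- p$red_intensity
    hl <- max(p$length_mean / px / 2 - radius_px, 1)
    add <- function(pxs, ratio) {
      red2d[pxs] <<- rr
      green2d[pxs] <<- ratio * rr / 200
    }
    # border-touching rod (truncated)
    b <- capsule_pixels(1, nx / 2, pi / 2, hl, radius_px, ny, nx)
    add(b, p$ratio_mean)
    # fused pair (ramified): two rods crossing at one point
    fy <- pad + 4; fx <- pad + 4
    f1 <- capsule_pixels(fy + hl, fx + hl, pi / 4, hl, radius_px, ny, nx)
    f2 <- capsule_pixels(fy + hl, fx + hl, 3 * pi / 4, hl, radius_px, ny, nx)
    add(rbind(f1, f2), p$ratio_mean)
    # single bright pixel: a detector hot pixel, injected after the PSF
    # blur (see below) so it stays one pixel wide like a real PMT spike
    spy <- pad + 4; spx <- nx - pad - 4
    # oversized aggregate: disk of ~30 um^2
    og <- capsule_pixels(ny - pad - 40, nx - pad - 40, 0, 0.5,
                         sqrt(30 / pi) / px, ny, nx)
    add(og, p$ratio_mean)
    decoys <- data.frame(
      kind = c("truncated", "ramified", "size_small", "size_large"),
      y_px = c(1, fy + hl, spy, ny - pad - 40),
      x_px = c(nx / 2, fx + hl, spx, nx - pad - 40))
  }

  nz <- p$n_planes
  zc <- (nz + 1L) %/% 2L
  to_stack <- function(img2d) {
    st <- array(0, dim = c(ny, nx, nz))
    st[, , zc] <- img2d
    blur_gaussian(st, c(fwhm_to_sigma(p$psf_fwhm_xy) / px,
                        fwhm_to_sigma(p$psf_fwhm_xy) / px,
                        fwhm_to_sigma(p$psf_fwhm_z) / p$z_step))
  }
  green <- to_stack(green2d)
  red <- to_stack(red2d)
  if (p$decoys) {
    spy <- decoys$y_px[decoys$kind == "size_small"]
    spx <- decoys$x_px[decoys$kind == "size_small"]
    red[spy, spx, zc] <- 12 * p$red_intensity
    green[spy, spx, zc] <- p$ratio_mean * 12 * p$red_intensity / 200
  }
  if (p$noise_level > 0) {
    green <- add_shot_noise(green, p$noise_level, p$read_noise_sd)
    red <- add_shot_noise(red, p$noise_level, p$read_noise_sd)
  }

  truth <- list(cell_mask = cell,
                particles = particles,
                decoys = decoys,
                cell_area_um2 = sum(cell) * px^2,
                total_mito_area_um2 = sum(particles$area_um2),
                focal_plane = zc,
                pre_blur = list(green = green2d, red = red2d))
  structure(list(green = green, red = red, truth = truth, params = p),
            class = "jc1_scene")
}

#' Generate a ground-truthed MitoTracker image
#'
#' Single-channel 2-D rendering of a mitochondrially stained cell: rods at
#' `mito_intensity`, a dim cytosolic level inside the cell, and a nonzero
#' extracellular background so that background estimation is testable. The
#' truth records the integrated pre-noise fluorescence inside the cell mask.
#'
#' @param params A [scene_params()] object.
#' @param mito_intensity Rod amplitude before blurring.
#' @param cytosol_intensity Diffuse in-cell amplitude.
#' @param background Extracellular amplitude.
#' @return List of class `mitotracker_image`: `image` (matrix), `truth`
#'   (with `integrated_intensity`, the pre-noise background-free sum inside
#'   the cell mask), `params`.
#' @export
generate_mitotracker_image <- function(params, mito_intensity = 600,
                                       cytosol_intensity = 30,
                                       background = 10) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  p$n_planes <- 1L
  scene <- generate_jc1_stack(scene_params(
    cell_area = p$cell_area, n_mitochondria = p$n_mitochondria,
    length_mean = p$length_mean, length_sd = p$length_sd,
    ratio_mean = 200, ratio_sd = 0, pixel_size_xy = p$pixel_size_xy,
    z_step = p$z_step, n_planes = 1L, psf_fwhm_xy = p$psf_fwhm_xy,
    psf_fwhm_z = p$psf_fwhm_z, rod_diameter = p$rod_diameter,
    red_intensity = mito_intensity, noise_level = 0,
    margin = p$margin, seed = p$seed))
  img <- scene$red[, , 1]
  cell <- scene$truth$cell_mask
  img <- img + cytosol_intensity * cell + background * !cell
  truth <- scene$truth
  truth$integrated_intensity <- sum(img[cell])
  truth$background <- background
  if (p$noise_level > 0)
    img <- add_shot_noise(img, p$noise_level, p$read_noise_sd)
  structure(list(image = img, truth = truth,
                 params = p), class = "mitotracker_image")
}
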