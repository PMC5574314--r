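#' Extract per-bead intensity profiles from a bead stack
#'
#' For each bead position, cuts a window around the local intensity
#' maximum and returns background-subtracted 1-D profiles along X, Y and Z
#' through that maximum. The per-profile background is the median of the
#' outer 20 percent of samples at each end. Beads whose window would cross
#' the stack border are skipped with a warning.
#'
#' @param beads A `bead_stack` (or any list with `stack`, `positions`,
#'   `pixel_size_xy`, `z_step`).
#' @param window Half-width of the extraction window in um (lateral; the
#'   axial half-width is scaled by the axial/lateral sampling ratio so the
#'   profile covers the same physical span).
#' @return List of class `bead_profiles` with elements `x`, `y`, `z`
#'   (lists of numeric profiles), `pixel_size_xy`, `z_step`,
#'   `n_beads_used`.
#' @export
extract_bead_profiles <- function(beads, window = 1.5) {
  st <- beads$stack
  d <- dim(st)
  if (is.null(d) || length(d) != 3 || any(d == 0) || nrow(beads$positions) == 0)
    stopf("extract_bead_profiles: empty stack or no bead positions")
  px <- beads$pixel_size_xy; dz <- beads$z_step
  wxy <- ceiling(window / px)
  wz <- ceiling(window / dz)
  profs <- list(x = list(), y = list(), z = list())
  used <- 0L
  for (i in seq_len(nrow(beads$positions))) {
    cy <- round(beads$positions$y_um[i] / px)
    cx <- round(beads$positions$x_um[i] / px)
    cz <- round(beads$positions$z_um[i] / dz)
    if (cy - wxy < 1 || cy + wxy > d[1] || cx - wxy < 1 || cx + wxy > d[2] ||
        cz - wz < 1 || cz + wz > d[3]) {
      warning(sprintf("bead %d too close to border; skipped", i),
              call. = FALSE)
      next
    }
    sub <- st[(cy - wxy):(cy + wxy), (cx - wxy):(cx + wxy),
              (cz - wz):(cz + wz)]
    m <- arrayInd(which.max(sub), dim(sub))
    strip_bg <- function(v) {
      k <- max(1L, floor(0.2 * length(v) / 2))
      v - median(c(head(v, k), tail(v, k)))
    }
    profs$y[[length(profs$y) + 1L]] <- strip_bg(sub[, m[2], m[3]])
    profs$x[[length(profs$x) + 1L]] <- strip_bg(sub[m[1], , m[3]])
    profs$z[[length(profs$z) + 1L]] <- strip_bg(sub[m[1], m[2], ])
    used <- used + 1L
  }
  if (used == 0L) stopf("extract_bead_profiles: no usable beads")
  structure(list(x = profs$x, y = profs$y, z = profs$z,
                 pixel_size_xy = px, z_step = dz, n_beads_used = used),
            class = "bead_profiles")
}

#' Average peak-aligned bead profiles
#'
#' Profiles are aligned by the centre of mass of their top 20 percent
#' intensities (rounded to the nearest pixel, accommodating sub-pixel bead
#' positions) and averaged pointwise.
#'
#' @param profiles List of equal-length numeric profiles.
#' @return The mean profile (same length as the inputs).
#' @export
average_profiles <- function(profiles) {
  if (length(profiles) == 0) stopf("average_profiles: empty profile list")
  n <- unique(vapply(profiles, length, 1L))
  if (length(n) != 1) stopf("average_profiles: profiles differ in length")
  ctr <- (n + 1) / 2
  aligned <- lapply(profiles, function(p) {
    thr <- max(p) - 0.2 * (max(p) - min(p))
    top <- p >= thr
    com <- sum(seq_len(n)[top] * p[top]) / sum(p[top])
    shift <- round(com - ctr)
    if (shift == 0) return(p)
    out <- rep(NA_real_, n)
    src <- seq_len(n) + shift
    ok <- src >= 1 & src <= n
    out[ok] <- p[src[ok]]
    out
  })
  colMeans(do.call(rbind, aligned), na.rm = TRUE)
}

#' Fit a Gaussian and report sigma and FWHM
#'
#' Least-squares fit of `b + a * exp(-(x - m)^2 / (2 s^2))` to a 1-D
#' profile; FWHM is `2 sqrt(2 ln 2) s`.
#'
#' @param profile Numeric profile with a single dominant maximum.
#' @param pixel_size Physical sample spacing of the profile (um).
#' @return List with `sigma` and `fwhm` in um.
#' @export
fit_fwhm <- function(profile, pixel_size) {
  n <- length(profile)
  if (n < 5) stopf("fit_fwhm: profile too short")
  if (diff(range(profile)) <= 0 ||
      diff(range(profile)) < 1e-9 * max(abs(profile), 1))
    stopf("fit_fwhm: flat profile")
  x <- seq_len(n)
  b0 <- min(profile); a0 <- max(profile) - b0
  m0 <- which.max(profile)
  w <- pmax(profile - b0, 0)
  s0 <- sqrt(sum(w * (x - m0)^2) / sum(w))
  s0 <- max(s0, 0.5)
  fit <- tryCatch(
    nls(profile ~ b + a * exp(-(x - m)^2 / (2 * s^2)),
        start = list(b = b0, a = a0, m = m0, s = s0),
        # scaleOffset keeps the convergence test meaningful on noise-free
        # (zero-residual) profiles
        control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) stopf("fit_fwhm: Gaussian fit failed (%s)",
                              conditionMessage(e)))
  s <- abs(coef(fit)[["s"]]) * pixel_size
  list(sigma = s, fwhm = sigma_to_fwhm(s))
}

#' Estimate the PSF from a bead stack
#'
#' End-to-end characterization: profile extraction, peak-aligned
#' averaging over beads, and Gaussian fitting, separately for the lateral
#' (X and Y pooled) and axial (Z) directions.
#'
#' @param beads A `bead_stack`.
#' @param window Extraction window half-width in um.
#' @return List of class `psf_estimate`: `fwhm_xy`, `fwhm_z`, `sigma_xy`,
#'   `sigma_z` (um) and `n_beads_used`.
#' @export
estimate_psf <- function(beads, window = 1.5) {
  pr <- extract_bead_profiles(beads, window)
  lat <- fit_fwhm(average_profiles(c(pr$x, pr$y)), pr$pixel_size_xy)
  axi <- fit_fwhm(average_profiles(pr$z), pr$z_step)
  structure(list(fwhm_xy = lat$fwhm, fwhm_z = axi$fwhm,
                 sigma_xy = lat$sigma, sigma_z = axi$sigma,
                 n_beads_used = pr$n_beads_used),
            class = "psf_estimate")
}

#' Construct a PSF description directly from known widths
#'
#' Convenience constructor used when the PSF is known (e.g. the synthetic
#' generator's own blur) rather than measured from beads.
#'
#' @param fwhm_xy,fwhm_z FWHM in um.
#' @return A `psf_estimate` (with `n_beads_used = 0`).
#' @export
psf_from_fwhm <- function(fwhm_xy, fwhm_z) {
  if (fwhm_xy <= 0 || fwhm_z <= 0) stopf("FWHM values must be positive")
  structure(list(fwhm_xy = fwhm_xy, fwhm_z = fwhm_z,
                 sigma_xy = fwhm_to_sigma(fwhm_xy),
                 sigma_z = fwhm_to_sigma(fwhm_z),
                 n_beads_used = 0L),
            class = "psf_estimate")
}
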