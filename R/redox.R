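#' Per-frame roGFP1 ratio trace
#'
#' Per-frame excitation ratio `R = mean(F395 in mask) / mean(F470 in
#' mask)`. Frames whose F470 mean is zero carry no ratio information and
#' are flagged invalid (`NA`).
#'
#' @param f395,f470 Arrays `[y, x, frame]` of equal dimensions (or a
#'   `rogfp_series` as the first argument, in which case `f470`, `mask`
#'   and `epochs` are taken from it).
#' @param mask Logical matrix selecting the cell.
#' @param epochs Optional character vector of per-frame epoch labels.
#' @param frame_rate_hz Acquisition rate, stored for reference.
#' @return List of class `rogfp_trace`: `ratios`, `mean_f395`,
#'   `mean_f470`, `epochs`, `frame_rate_hz`.
#' @export
compute_ratio_trace <- function(f395, f470 = NULL, mask = NULL,
                                epochs = NULL, frame_rate_hz = 0.1) {
  if (inherits(f395, "rogfp_series")) {
    s <- f395
    f395 <- s$f395; f470 <- s$f470
    mask <- mask %||% s$cell_mask
    epochs <- epochs %||% s$epochs
    frame_rate_hz <- s$params$frame_rate_hz
  }
  if (!identical(dim(f395), dim(f470)))
    stopf("compute_ratio_trace: frame sequences differ in shape or length")
  if (is.null(mask) || !any(mask))
    stopf("compute_ratio_trace: cell mask is empty")
  nf <- dim(f395)[3]
  m395 <- m470 <- numeric(nf)
  for (t in seq_len(nf)) {
    m395[t] <- mean(f395[, , t][mask])
    m470[t] <- mean(f470[, , t][mask])
  }
  ratios <- ifelse(m470 == 0, NA_real_, m395 / m470)
  if (anyNA(ratios))
    warning("frames with zero F470 flagged invalid", call. = FALSE)
  if (!is.null(epochs) && length(epochs) != nf)
    stopf("compute_ratio_trace: epoch labels do not match frame count")
  structure(list(ratios = ratios, mean_f395 = m395, mean_f470 = m470,
                 epochs = epochs, frame_rate_hz = frame_rate_hz),
            class = "rogfp_trace")
}

#' Extract the in-situ calibration from a trace
#'
#' Endpoint ratios from the saturating plateaus: `r_ox` and `r_red` are
#' the mean ratios over the last `plateau_fraction` of the oxidant and
#' reductant epochs (the early part of each epoch is discarded to avoid
#' transition kinetics), and the instrument factor is the corresponding
#' F470 plateau quotient `I470(ox) / I470(red)`.
#'
#' @param trace A labeled `rogfp_trace`.
#' @param plateau_fraction Trailing fraction of each plateau used
#'   (default 0.5).
#' @param min_frames Minimum frames required per plateau epoch.
#' @return List of class `calibration_result`: `r_red`, `r_ox`,
#'   `instrument_factor`.
#' @export
extract_calibration <- function(trace, plateau_fraction = 0.5,
                                min_frames = 5) {
  stopifnot(inherits(trace, "rogfp_trace"))
  if (is.null(trace$epochs)) stopf("extract_calibration: trace is unlabeled")
  tail_idx <- function(epoch) {
    idx <- which(trace$epochs == epoch)
    if (length(idx) < min_frames)
      stopf("extract_calibration: epoch '%s' missing or too short (< %d frames)",
            epoch, min_frames)
    idx[idx > idx[length(idx)] - max(1, floor(plateau_fraction * length(idx)))]
  }
  iox <- tail_idx("oxidant")
  ired <- tail_idx("reductant")
  r_ox <- mean(trace$ratios[iox], na.rm = TRUE)
  r_red <- mean(trace$ratios[ired], na.rm = TRUE)
  instrument_factor <- mean(trace$mean_f470[iox]) / mean(trace$mean_f470[ired])
  if (r_red >= r_ox)
    stopf("calibration failure: reduced-endpoint ratio (%.3f) is not below the oxidized endpoint (%.3f)",
          r_red, r_ox)
  structure(list(r_red = r_red, r_ox = r_ox,
                 instrument_factor = instrument_factor),
            class = "calibration_result")
}

#' Degree of sensor oxidation from a calibrated ratio
#'
#' The standard excitation-ratiometric form with an instrument factor
#' correcting for the 470 nm channel's sensitivity change:
#' `OxD = (R - r_red) / (IF * (r_ox - R) + (R - r_red))`. Values are
#' clamped to `[0, 1]`; inputs outside the calibrated range are flagged
#' via the `clamped` attribute.
#'
#' @param R Ratio value(s).
#' @param cal A `calibration_result`.
#' @return OxD in `[0, 1]` (vectorized), attribute `clamped` marking
#'   out-of-range inputs.
#' @export
compute_oxd <- function(R, cal) {
  if (cal$r_ox == cal$r_red) stopf("compute_oxd: degenerate calibration")
  oxd <- (R - cal$r_red) /
    (cal$instrument_factor * (cal$r_ox - R) + (R - cal$r_red))
  clamped <- oxd < 0 | oxd > 1
  oxd <- pmin(pmax(oxd, 0), 1)
  attr(oxd, "clamped") <- clamped
  oxd
}

#' Nernst reduction potential of the sensor
#'
#' `E = E0 - (R T / 2 F) * ln((1 - OxD) / OxD)` in mV, for the
#' two-electron roGFP1 thiol couple. The midpoint potential defaults to
#' -291 mV (roGFP1) and the temperature to 310.15 K (cells imaged at
#' 37 C); both are configurable. Undefined at OxD of exactly 0 or 1.
#'
#' @param oxd Degree of oxidation strictly inside (0, 1).
#' @param e0_mV Sensor midpoint potential (mV).
#' @param temperature_K Absolute temperature (K).
#' @return Potential in mV (vectorized).
#' @export
compute_potential <- function(oxd, e0_mV = -291, temperature_K = 310.15) {
  if (any(oxd <= 0 | oxd >= 1))
    stopf("compute_potential: potential undefined at OxD endpoints")
  R_gas <- 8.314462618   # J / (mol K)
  faraday <- 96485.33212 # C / mol
  e0_mV - 1000 * (R_gas * temperature_K / (2 * faraday)) *
    log((1 - oxd) / oxd)
}

#' End-to-end redox quantification for one cell
#'
#' Baseline ratio (mean over the baseline epoch), in-situ calibration
#' from the plateau epochs, degree of oxidation and reduction potential.
#'
#' @param trace A labeled `rogfp_trace`.
#' @param e0_mV,temperature_K Passed to [compute_potential()].
#' @param plateau_fraction Passed to [extract_calibration()].
#' @return List of class `redox_state`: `baseline_ratio`, `oxd`, `e_mV`,
#'   `calibration`, `e0_mV`, `temperature_K`.
#' @export
quantify_redox <- function(trace, e0_mV = -291, temperature_K = 310.15,
                           plateau_fraction = 0.5) {
  cal <- extract_calibration(trace, plateau_fraction)
  base <- mean(trace$ratios[trace$epochs == "baseline"], na.rm = TRUE)
  oxd <- as.numeric(compute_oxd(base, cal))
  e <- if (oxd > 0 && oxd < 1)
    compute_potential(oxd, e0_mV, temperature_K) else NA_real_
  structure(list(baseline_ratio = base, oxd = oxd, e_mV = e,
                 calibration = cal, e0_mV = e0_mV,
                 temperature_K = temperature_K),
            class = "redox_state")
}
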