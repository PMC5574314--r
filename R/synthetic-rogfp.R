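#' Parameters for a synthetic roGFP1 excitation-ratio series
#'
#' Describes one cell's alternating 395 nm / 470 nm excitation recording
#' with a baseline epoch followed by a saturating-oxidant (H2O2) plateau
#' and a saturating-reductant (DTT) plateau, as used for in-situ sensor
#' calibration.
#'
#' The default endpoint ratios (`r_red = 0.5`, `r_ox = 2.0`) bracket the
#' typical roGFP1 dynamic range, and the default instrument factor
#' (0.5737, the 470 nm-excited fluorescence at full oxidation relative to
#' full reduction; oxidation dims the 470 nm band so the factor is below
#' one) is chosen so that a resting ratio of 0.92 and a degree of
#' oxidation of 40.4 % are mutually consistent under these endpoints.
#'
#' @param true_oxd True degree of sensor oxidation in `[0, 1]`.
#' @param r_red,r_ox Fully reduced / fully oxidized endpoint ratios
#'   (`r_red < r_ox`).
#' @param instrument_factor I470(ox) / I470(red), > 0.
#' @param epoch_lengths Named integer vector: frames in the `baseline`,
#'   `oxidant` and `reductant` epochs.
#' @param noise_sd SD of the per-frame multiplicative excitation noise
#'   applied independently to each channel.
#' @param f470_red 470 nm-excited intensity at full reduction (arbitrary
#'   units).
#' @param frame_dim Frame size in pixels (the cell fills a centred disk).
#' @param frame_rate_hz Acquisition rate (default 0.1 Hz).
#' @param seed Integer seed.
#' @return List of class `rogfp_series_params`.
#' @export
rogfp_series_params <- function(true_oxd, r_red = 0.5, r_ox = 2.0,
                                instrument_factor = 0.5737,
                                epoch_lengths = c(baseline = 30,
                                                  oxidant = 20,
                                                  reductant = 20),
                                noise_sd = 0.02, f470_red = 100,
                                frame_dim = c(24, 24),
                                frame_rate_hz = 0.1, seed = NULL) {
  if (true_oxd < 0 || true_oxd > 1) stopf("true_oxd must lie in [0, 1]")
  if (r_red >= r_ox) stopf("r_red must be < r_ox")
  if (instrument_factor <= 0) stopf("instrument_factor must be > 0")
  need <- c("baseline", "oxidant", "reductant")
  if (!all(need %in% names(epoch_lengths)))
    stopf("epoch_lengths must name baseline, oxidant and reductant")
  structure(list(true_oxd = true_oxd, r_red = r_red, r_ox = r_ox,
                 instrument_factor = instrument_factor,
                 epoch_lengths = epoch_lengths[need], noise_sd = noise_sd,
                 f470_red = f470_red, frame_dim = frame_dim,
                 frame_rate_hz = frame_rate_hz, seed = seed),
            class = "rogfp_series_params")
}

# Ratio analytically implied by a degree of oxidation under given
# endpoints and instrument factor (inverse of the OxD formula).
oxd_to_ratio <- function(oxd, r_red, r_ox, instrument_factor) {
  ((1 - oxd) * r_red + oxd * instrument_factor * r_ox) /
    ((1 - oxd) + oxd * instrument_factor)
}

#' Generate a synthetic roGFP1 series with calibration epochs
#'
#' Produces paired F395 / F470 frame sequences (epoch order: baseline,
#' then the saturating-H2O2 plateau, then the saturating-DTT plateau).
#' The noise-free baseline ratio equals the ratio analytically implied by
#' (`true_oxd`, `r_red`, `r_ox`, `instrument_factor`); the oxidant epoch
#' sits at `r_ox` and the reductant epoch at `r_red`. The 470 nm level
#' mixes linearly between its reduced and oxidized endpoints with the
#' oxidized fraction, so the instrument factor round-trips exactly.
#'
#' @param params A [rogfp_series_params()] object.
#' @return List of class `rogfp_series`: `f395`, `f470` (arrays
#'   `[y, x, frame]`), `epochs` (character per frame), `cell_mask`,
#'   `params`.
#' @export
generate_rogfp1_series <- function(params) {
  stopifnot(inherits(params, "rogfp_series_params"))
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  nf <- sum(p$epoch_lengths)
  epochs <- rep(names(p$epoch_lengths), p$epoch_lengths)
  ny <- p$frame_dim[1]; nx <- p$frame_dim[2]
  yy <- matrix(seq_len(ny) - (ny + 1) / 2, ny, nx)
  xx <- matrix(seq_len(nx) - (nx + 1) / 2, ny, nx, byrow = TRUE)
  cell <- sqrt(yy^2 + xx^2) <= min(ny, nx) * 0.4

  oxd_of <- c(baseline = p$true_oxd, oxidant = 1, reductant = 0)
  f470_level <- p$f470_red * ((1 - oxd_of) + oxd_of * p$instrument_factor)
  ratio_level <- oxd_to_ratio(oxd_of, p$r_red, p$r_ox, p$instrument_factor)

  f395 <- array(0, dim = c(ny, nx, nf))
  f470 <- array(0, dim = c(ny, nx, nf))
  for (t in seq_len(nf)) {
    e <- epochs[t]
    g470 <- if (p$noise_sd > 0) max(1 + rnorm(1, 0, p$noise_sd), 0.2) else 1
    g395 <- if (p$noise_sd > 0) max(1 + rnorm(1, 0, p$noise_sd), 0.2) else 1
    f470[, , t] <- cell * f470_level[e] * g470
    f395[, , t] <- cell * f470_level[e] * ratio_level[e] * g395
  }
  structure(list(f395 = f395, f470 = f470, epochs = epochs,
                 cell_mask = cell, params = p),
            class = "rogfp_series")
}
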