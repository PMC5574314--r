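#' Registered dual-emission JC-1 stack
#'
#' Container for the two spectrally separated JC-1 emission channels:
#' green (~530 nm, monomers, depolarized mitochondria) and red (~590 nm,
#' J-aggregates, polarized mitochondria). Channels must share shape and
#' registration; intensities must be non-negative.
#'
#' @param green,red Numeric arrays (2-D or 3-D) of identical dimensions.
#' @param pixel_size_xy Lateral sampling (um/pixel).
#' @param z_step Axial sampling (um/plane).
#' @return List of class `channel_stack`.
#' @export
channel_stack <- function(green, red, pixel_size_xy = 0.08, z_step = 0.25) {
  if (!identical(dim(green), dim(red)))
    stopf("channel_stack: green and red dimensions differ")
  if (min(green) < 0 || min(red) < 0)
    stopf("channel_stack: intensities must be >= 0")
  structure(list(green = green, red = red,
                 pixel_size_xy = pixel_size_xy, z_step = z_step),
            class = "channel_stack")
}

as_channel_stack <- function(x) {
  if (inherits(x, "channel_stack")) return(x)
  if (inherits(x, "jc1_scene"))
    return(channel_stack(x$green, x$red, x$params$pixel_size_xy,
                         x$params$z_step))
  stopf("expected a channel_stack or jc1_scene")
}

#' Emission-ratiometric JC-1 image
#'
#' Computes the per-voxel membrane-potential readout
#' `R = green * scaling / red`. The scaling constant (default 200) was
#' introduced so that typical ratios span an 8-bit pseudocolor palette; it
#' is a pure display-era convention retained for comparability and the
#' analysis keeps the values as floating point. No background subtraction
#' is applied (with 2-photon excitation, out-of-focus background is
#' negligible). Voxels with zero red signal carry no membrane-potential
#' information: they are flagged invalid (`NA` in `values`) and excluded
#' from all downstream statistics rather than clamped.
#'
#' @param stack A [channel_stack()] (or a `jc1_scene`).
#' @param scaling Positive scaling constant, default 200.
#' @return List of class `ratio_image`: `values` (array, `NA` where
#'   invalid), `invalid` (logical array, `TRUE` where red = 0),
#'   `scaling`, `pixel_size_xy`.
#' @export
jc1_ratio <- function(stack, scaling = 200) {
  stack <- as_channel_stack(stack)
  if (scaling <= 0) stopf("jc1_ratio: scaling must be > 0")
  invalid <- stack$red == 0
  values <- stack$green * scaling / stack$red
  values[invalid] <- NA_real_
  structure(list(values = values, invalid = invalid, scaling = scaling,
                 pixel_size_xy = stack$pixel_size_xy),
            class = "ratio_image")
}
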