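#' Cell area from a boundary mask
#'
#' Area of the (single, connected) circled cell region: pixel count times
#' pixel area.
#'
#' @param mask Logical matrix, one connected region.
#' @param pixel_size Lateral pixel size (um).
#' @return Area in um^2.
#' @export
cell_area <- function(mask, pixel_size) {
  stopifnot(is.matrix(mask))
  if (!any(mask)) stopf("cell_area: empty mask")
  if (max(.label_components(mask)) != 1L)
    stopf("cell_area: mask must be one connected region")
  sum(mask) * pixel_size^2
}

#' Total mitochondrial mass of a cell
#'
#' Sum of all above-threshold pixel areas inside the cell, in um^2 — the
#' area of every JC-1-labeled structure on the collapsed plane, including
#' aggregates and other components excluded from single-particle
#' statistics (they still contribute to mass). The source data are
#' acquired as volumes but analysed on the collapsed plane, so this
#' "mass" carries area units; a voxel-count pseudo-volume
#' (`area * z-step`) is attached for completeness.
#'
#' @param mito_mask Logical matrix of above-threshold pixels, already
#'   restricted to the cell region.
#' @param pixel_size Lateral pixel size (um).
#' @param z_step Axial step (um), used only for the attached pseudo-volume.
#' @return Mass in um^2 with attribute `volume_um3`.
#' @export
total_mito_mass <- function(mito_mask, pixel_size, z_step = 0.25) {
  stopifnot(is.matrix(mito_mask))
  m <- sum(mito_mask) * pixel_size^2
  attr(m, "volume_um3") <- m * z_step
  m
}

#' Mitochondrial density
#'
#' Mitochondrial content normalized to cell size: the quotient of a
#' per-cell mass (um^2) or particle count by the cell area. Count-based
#' density has units per um^2; area-based density is a dimensionless area
#' fraction.
#'
#' @param mass_or_count Total mitochondrial mass (um^2) or particle count.
#' @param cell_area Cell area (um^2), > 0.
#' @return The quotient.
#' @export
mito_density <- function(mass_or_count, cell_area) {
  if (cell_area <= 0) stopf("mito_density: cell area must be > 0")
  as.numeric(mass_or_count) / cell_area
}

#' Cell-normalized MitoTracker intensity
#'
#' Background-subtracted integrated MitoTracker fluorescence inside the
#' cell mask divided by the cell area. The background is the median
#' intensity outside all cell masks (the staining protocol gives no
#' instrument background reference).
#'
#' @param image Numeric matrix.
#' @param mask Logical matrix: the cell (or union of cells for background
#'   purposes).
#' @param pixel_size Lateral pixel size (um).
#' @return Intensity per um^2.
#' @export
mitotracker_normalized_intensity <- function(image, mask, pixel_size) {
  stopifnot(is.matrix(image), is.matrix(mask))
  if (!any(mask)) stopf("mitotracker_normalized_intensity: empty cell mask")
  if (all(mask))
    stopf("mitotracker_normalized_intensity: mask covers the whole image; no background estimate")
  bg <- median(image[!mask])
  integrated <- sum(image[mask] - bg)
  integrated / (sum(mask) * pixel_size^2)
}

#' Per-cell morphometry from a segmentation
#'
#' Collects the per-cell quantities: cell area, total mitochondrial mass
#' (all above-threshold pixels inside the cell), retained particle count,
#' and both density variants. The identity
#' `density_count * cell_area == particle_count` holds exactly on every
#' row.
#'
#' @param seg A `segmentation` from [segment_particles()].
#' @param cell_mask Logical matrix: the circled cell boundary (from ground
#'   truth or a user ROI).
#' @param pixel_size Lateral pixel size (um).
#' @return One-row data frame of class `cell_metrics`: `cell_area_um2`,
#'   `total_mito_area_um2`, `particle_count`, `density_count_per_um2`,
#'   `density_area_fraction`, `mean_particle_length_um`,
#'   `mean_particle_ratio`.
#' @export
cell_metrics <- function(seg, cell_mask, pixel_size) {
  ca <- cell_area(cell_mask, pixel_size)
  mass <- total_mito_mass(seg$mask & cell_mask, pixel_size)
  retained <- seg$records[seg$records$status == "retained", ]
  out <- data.frame(
    cell_area_um2 = ca,
    total_mito_area_um2 = as.numeric(mass),
    particle_count = nrow(retained),
    density_count_per_um2 = mito_density(nrow(retained), ca),
    density_area_fraction = mito_density(as.numeric(mass), ca),
    mean_particle_length_um = if (nrow(retained)) mean(retained$length_um)
      else NA_real_,
    mean_particle_ratio = if (nrow(retained))
      mean(retained$mean_ratio, na.rm = TRUE) else NA_real_)
  class(out) <- c("cell_metrics", class(out))
  out
}
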