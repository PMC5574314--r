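---
title: "Methods: ratiometric quantification of mitochondrial membrane potential, mass and cytosolic redox state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratiometric quantification of mitochondrial membrane potential, mass and cytosolic redox state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoquant)
```

## The measurement problem

Cultured astrocytes loaded with the carbocyanine dye JC-1 report the
membrane potential of each mitochondrion through the balance of two
emission bands: green-fluorescent monomers (~530 nm) dominate in
depolarized mitochondria, while red-fluorescent J-aggregates (~590 nm)
only form in strongly polarized mitochondria (below roughly −140 mV).
The per-voxel emission ratio

$$R_\mathrm{JC\text{-}1} = \frac{F_\mathrm{green} \times 200}{F_\mathrm{red}}$$

is therefore a relative readout of $\Delta\Psi_m$ that is independent of
dye loading and local mitochondrial content. The factor 200 is a display
convention (it spreads typical ratios over an 8-bit pseudocolor
palette); `jc1_ratio()` keeps it for comparability but stores floating
point values. No background subtraction is applied: with two-photon
excitation, out-of-focus background is negligible, and a zero-red voxel
carries no potential information, so such voxels are flagged invalid
rather than clamped.

On top of the voxel-level ratio, the package implements a
single-mitochondrion analysis (detection, spatial filtering,
morphometry), per-cell mass and density metrics, a point-spread-function
(PSF) characterization from sub-resolution beads, cytosolic redox
quantification with the roGFP1 excitation ratio, and the two-group
statistics used for genotype and drug contrasts. Because the original
cultures are not available, a ground-truthed synthetic-microscopy
generator stands in for them: every stage is validated by parameter
recovery against known truth.

## Single-particle pipeline

The pipeline mirrors a semiautomated routine built around a collapsed
focal plane:

1. **Deconvolution.** The acquisition-era blind deconvolution is a
   closed commercial product; the package substitutes deterministic
   Richardson–Lucy restoration (`deconvolve()`) driven by the PSF
   measured from beads. Default 20 iterations (8 in the fast test
   configurations); `iterations = 0` is the identity. The restoration is
   non-negative and conserves per-channel flux to within a percent.
2. **Focal plane.** By-eye plane selection is automated as the plane of
   maximum integrated summed-channel intensity, ties broken toward the
   lower index (`select_focal_plane()`); a manual override argument
   exists.
3. **Collapse.** The focal plane is averaged with its two upper and two
   lower neighbours (`collapse_planes()`, half-window configurable). The
   *mean* (not a maximum projection) is used because it preserves the
   green/red proportion; the ratio is always computed on the collapsed
   channels, never by averaging per-plane ratios.
4. **Threshold.** A global Otsu threshold (256-bin histogram) on the
   summed-channel collapsed image separates mitochondria from
   background. Otsu was chosen because it is parameter-free; the method
   is recorded in the configuration.
5. **Spatial filtering.** Each 8-connected component gets exactly one
   status, assigned in priority order: `excluded_truncated` (touches the
   image margin), `excluded_size` (area outside 0.1–20 µm² — hot pixels
   and unresolvable aggregates), `excluded_ramified` (overlapping
   organelles), else `retained`.
6. **Measurement.** Retained particles are measured on the ratio image:
   area (pixel count × pixel area), mean ratio over valid voxels, and
   length.

### The ramified rule

"Overlapping with others" is qualitative; the package operationalizes it
on the component's morphological skeleton (Zhang–Suen thinning): a
particle is ramified if, after pruning spurs up to 2 px, the skeleton
has any branch point, or if solidity (area / convex-hull area) falls
below 0.6. Branch points are detected by the crossing-number criterion
*and* by endpoint excess (more than two line-ends), because thinning
can leave thick junction clusters in which no single pixel reaches a
crossing number of three. A bent rod has two endpoints and stays
retained; a crossing pair has four and is excluded. Both thresholds are
configurable in `pipeline_config()`.

### Length definition

Length is the geodesic length of the skeleton's longest path, extended
from each end to the component boundary along the local path direction,
plus a one-pixel end-cap correction, converted to µm. The extension step
undoes a systematic artifact of thinning: skeletons of rods retract by
about half the rod width at each tip, which at an 0.4 µm rod diameter
would bias lengths by ~15 %. On an exact 30 × 5 px rod at 0.08 µm/px the
measure returns 2.4 µm within one pixel. On blurred, thresholded
synthetic rods the measured cohort mean runs ~5 % above the generator
mean — the above-threshold object extends slightly beyond the true tips
— which is inside the 10 % recovery tolerance and reported as-is, not
recalibrated away.

Pixel indices are 0-based internally where geometry matters; physical
coordinates are pixel-centre × pixel size.

## PSF characterization

Sub-resolution (100 nm) beads are small against the optical resolution,
so their images *are* the PSF. `estimate_psf()` extracts
background-subtracted X/Y/Z profiles through each bead's intensity
maximum (per-profile background: median of the outer 20 % of samples),
aligns profiles on the centre of mass of their top-20 % intensities (to
absorb sub-pixel bead positions), averages them across beads, and fits a
Gaussian plus constant offset by least squares. FWHM $= 2\sqrt{2\ln 2}\,
\sigma$. Beads too close to the border are skipped with a warning. The
fit uses a convergence scale offset so that noise-free (zero-residual)
profiles converge cleanly. Lateral (X and Y pooled) and axial estimates
are reported separately; any wavelength dependence of the PSF is ignored
— one PSF per acquisition configuration.

## Cell-level morphometry

Cell boundaries come from ground truth (synthetic data) or a
user-supplied ROI mask; automatic cell segmentation is out of scope
because boundaries were circled manually in the emulated workflow.
Per cell, the package reports: area (µm²); total mitochondrial mass —
the summed area of *all* above-threshold pixels inside the cell,
including components excluded from single-particle statistics, since
aggregates still contribute mass; retained particle count; and density
in both variants, count/area (per µm²) and area/area (dimensionless).
The count-based variant is used for group comparisons — the published
density unit (per µm²) and its use alongside particle counts point to a
count-based quantity — but both are always emitted. The identity
`density_count × cell_area = particle_count` holds exactly on every
output row. "Mass" carries area units because the analysis lives on the
collapsed plane; a voxel pseudo-volume (area × z-step) is attached for
completeness. MitoTracker intensity is background-corrected by the
median intensity outside all cell masks (no instrument background
reference exists) and normalized to cell area.

## Redox quantification

Each roGFP1 series is an alternating 395/470 nm excitation sequence with
a baseline epoch followed by saturating H₂O₂ (full oxidation) and
saturating DTT (full reduction) plateaus. Per frame,
$R = \overline{F_{395}}/\overline{F_{470}}$ over the cell mask. The
calibration takes the mean ratio over the trailing half of each plateau
(the leading half is discarded to avoid transition kinetics; fraction
configurable) giving $R_\mathrm{ox}$ and $R_\mathrm{red}$, plus the
instrument factor $I_{470}^{ox}/I_{470}^{red}$ from the same frames.
The degree of oxidation uses the standard excitation-ratiometric form
with the instrument factor:

$$\mathrm{OxD} = \frac{R - R_\mathrm{red}}
{\,I\,(R_\mathrm{ox} - R) + (R - R_\mathrm{red})}$$

clamped to [0, 1] with out-of-range inputs flagged. The source
literature cites this formula rather than printing it; the
instrument-factor variant was chosen because the 470 nm band's
sensitivity change is what makes the uncorrected two-point formula
biased, and the factor is measurable from the same calibration frames at
no cost. The reduction potential is the two-electron Nernst form

$$E = E_0 - \frac{RT}{2F}\,\ln\frac{1-\mathrm{OxD}}{\mathrm{OxD}}$$

with $E_0 = -291$ mV (roGFP1 midpoint) and $T = 310.15$ K (cells at
37 °C) as configurable defaults; 298.15 K is available. $E$ is undefined
at OxD endpoints and errors there.

Default calibration constants of the *generator* are
$R_\mathrm{red} = 0.5$, $R_\mathrm{ox} = 2.0$ (a typical roGFP1 dynamic
range) and instrument factor 0.5737. The factor is below one because
oxidation dims the 470 nm-excited band; its default value is the unique
number that makes a resting ratio of 0.92 and a resting OxD of 40.4 %
mutually consistent under these endpoints, so the wild-type-like
simulated world is internally coherent.

## The synthetic generator: what it does and does not emulate

`generate_jc1_stack()` renders a flatly grown astrocyte as a smoothed
random blob (low-order radial Fourier outline) of requested area, filled
with capsule-shaped rods of fixed 0.4 µm diameter — a typical
mitochondrial width; the emulated data offer no diameter statistics —
whose lengths and JC-1 ratios are drawn from normal distributions
truncated at zero (only means/SDs are available). Rods are placed
without overlap and with a 0.25 µm clearance margin inside the cell, in
the central plane of a thin slab; the scene is blurred with a separable
3-D Gaussian PSF (only FWHM information exists about the real PSF) and
degraded with Poisson shot noise on a configurable photon scale plus
Gaussian read noise — PMT/CCD detection physics, not a fitted noise
model. Before blurring, each rod's channels satisfy
`green × 200 / red = ratio` exactly, so ratio recovery is testable
against per-particle truth. An optional decoy mode injects the objects
the spatial filter must reject: a border-clipped rod, a crossing rod
pair, an oversized aggregate, and a detector hot pixel — the hot pixel
is added *after* the PSF blur because real single-pixel artifacts are
detector events, not optical ones.

The generator deliberately does **not** model: spontaneous
$\Delta\Psi_m$ flickering or any temporal dynamics; a 3-D cell-thickness
profile (rods sit in one plane); neurons or neighbouring cells; spatial
background structure from interstitial dye; dye-loading kinetics or
photobleaching; curved or branched (genuinely ramified) mitochondria as
*truth* objects. A green recovery test therefore establishes that the
pipeline correctly inverts the stated forward model at realistic noise
— not that it would segment arbitrarily dense, dynamic or
out-of-plane mitochondrial networks.

Default scene intensities (rod red amplitude 800, shot-noise scale 1,
read noise SD 2) give post-collapse single-pixel SNR around 10, a
mid-range two-photon operating point.

## Desk scaling of the recovery cohorts

The validation cohorts are rendered at 0.16 µm/pixel with cell areas of
900–3600 µm², smaller than the emulated acquisitions (0.08 µm/pixel,
~4700 µm² cells), because pipeline cost grows with the pixel count while
every recovered quantity — particle count per cell, length in µm,
count-based density, ratios — is independent of the field of view.
Length recovery alone runs at the native 0.08 µm/pixel since length
measurement is the one place where sampling enters. Counts per cell are
drawn with an SD of 10 % of the mean: the recovery target is the cohort
mean, and the published between-cell dispersions (which reach 60 % of
the mean) would only inflate the variance of that mean without testing
anything further about the pipeline.

## Numerical choices

- Gaussian kernels are truncated at 3σ and normalized to unit sum;
  convolution uses reflecting borders, so flux is conserved on flat
  fields.
- Richardson–Lucy divides by the re-blurred estimate plus an epsilon of
  `1e-8 × max(image)` to avoid 0/0 in empty regions.
- Otsu uses a 256-bin histogram between the image extremes and errors on
  constant images (no threshold exists).
- Focal-plane ties break toward the lower plane index; `which.max`
  semantics, documented as the tie rule.
- Solidity uses the convex hull of pixel centres and is capped at 1
  (thin components have hull areas below their pixel count).
- Degenerate zero-variance groups in `compare_groups()` return t = 0,
  p = 1 when means agree and p = 0 when they differ, instead of the NaN
  a naive Welch formula would produce.
- Seeds: every generator takes an explicit seed and is bit-reproducible;
  multi-part simulations derive child seeds deterministically
  (`derive_seed()`), all below 2³¹.

## Known limitations

- The deconvolution surrogate is Richardson–Lucy with a *measured
  Gaussian* PSF, not blind deconvolution; restored images differ from
  the original commercial output in unknown ways.
- The length measure is validated on straight-to-gently-bent rods; on
  strongly curved mitochondria the end-extension step can clip.
- MitoTracker normalization assumes the extracellular median is a fair
  background; structured backgrounds violate this.
- Group comparisons treat cells as independent units (no culture- or
  animal-level nesting), mirroring the emulated analysis; a
  mixed-effects layer is out of scope.
- TIFF I/O is intentionally absent (no maintained TIFF reader in the
  supported dependency set); images interchange through a documented
  plain-text stack format (`write_stack_txt()`).
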