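---
title: "Methods: gradient-based particle metrology for SFM height maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gradient-based particle metrology for SFM height maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmetrics)
```

## The measurement problem

Scanning force microscopy (SFM/AFM) images biomolecules as a calibrated
height field $z(x, y)$ in nanometres. DNA molecules appear as smooth
ridges roughly 0.3–0.5 nm tall; protein complexes as blobs a few nm
tall. The quantities a molecular biologist wants from such an image are
geometric: the volume of a complex (a proxy for molecular mass), the
contour length of a DNA molecule or nucleoprotein filament, its apparent
width, the height along its backbone, and angles between segments.

Two practical obstacles shape the design. First, every instrument
vendor stores the calibration differently, so all readers normalize to
one container (`height_map`): a matrix of heights in nm plus the
lateral pixel size in nm/px. Second, biomolecules are dim compared to
typical image dynamic range and sit on a background that is never
perfectly flat, so segmentation by a plain intensity cut is fragile;
the package instead detects particles in the *gradient* domain.

## Particle detection

`detect_particles()` runs the pipeline:

1. **Sobel gradient magnitude.** The two 3×3 Sobel kernels give the
   horizontal and vertical derivatives; they are combined as
   $G = \sqrt{G_x^2 + G_y^2}$. Borders are handled by edge replication.
   Gradients are expressed in nm per *pixel*, not nm per nm, so a given
   threshold behaves identically across scan sizes.
2. **Thresholding.** The automatic base threshold is $4\times$ the
   root-mean-square of $G$ — a standard automatic Sobel-edge level that
   is deterministic and scale-covariant. The user's single tuning
   parameter, `threshold_factor`, multiplies this base; it corresponds
   to the stringency slider of interactive SFM analysis tools. Raw edge
   sets shrink monotonically as the factor grows.
3. **Morphology.** Closing (3×3 box) first, so broken edge rings are
   bridged; then hole filling, which turns each closed ring into a
   solid region; then opening (3×3 box) to delete isolated specks.
4. **Border suppression.** Any 8-connected component touching the image
   border is removed: a particle cut by the field of view cannot be
   measured.

The mask is *only* a selection device: every measurement (volume,
profiles, statistics) is evaluated on the unmodified heights.

Connectivity is 8-connected throughout, so thin diagonal DNA strands
stay single particles. Labels are numbered in row-major scan order and
the largest particle is selected for single-complex analysis, ties
resolved by scan order — deterministic by construction.

### Why a gradient, not an intensity cut

An intensity threshold at, say, 15% of the image maximum moves with any
residual background tilt; the gradient of a tilted plane is constant
and simply shifts the automatic base threshold. With a tilt of 20% of
the particle height across the image, the gradient mask of a test blob
is essentially unchanged (IoU ≈ 0.99 against the untilted mask) while
the 15%-of-max intensity mask collapses (IoU ≈ 0.1). The package keeps
`intensity_threshold_mask()` as the explicit comparison baseline.

A caveat that matters for calibration work: on a noiseless Gaussian
blob the gradient ring at `threshold_factor = 1` sits near $1.9\sigma$
from the centre, which clips roughly 17% of the analytic volume
$2\pi\sigma^2 A$. The slider exists precisely to set stringency: at
`threshold_factor = 0.3` the filled mask reaches $2.5{-}3\sigma$ and
volume recovery on clean synthetic blobs is within a few percent. On
noisy real images higher factors trade completeness for specificity,
and absolute volumes should in any case be calibrated against a
standard of known mass (`calibrate_to_kda()`).

## Volume and background

`estimate_background()` is the mean height outside all detected
particles; `particle_volume()` sums `(height − background) ×
pixel_area` over the selected particle. Adding any constant to the
whole image leaves the volume invariant, because the background shifts
by the same constant.

## Profiles along a traced path

A freehand trace is an ordered polyline in sub-pixel (row, col)
coordinates. `path_length()` applies the per-axis pixel sizes, so
anisotropic scans are handled. `height_profile()` resamples the path at
1 px arc steps (default) and reads heights by bilinear interpolation.

`width_profile()` measures the apparent width: at each resampled path
point it samples a cross-section orthogonal to the local tangent
(central difference — stable against freehand jitter) at 0.25 px steps,
and fits a four-parameter Gaussian $A e^{-(s-c)^2/2\sigma^2} + b$ by
Levenberg–Marquardt least squares. The baseline term matters because
real cross-sections sit on non-zero background. Initialisation is
amplitude = max−min, centre = argmax, σ from the half-maximum width of
the raw samples, baseline = min. A fit is rejected when the optimizer
fails, σ exceeds the window length, or the amplitude is not at least
twice the residual RMS; rejected sections are flagged and excluded from
the summary. The full width at half maximum is
$\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma \approx 2.355\,\sigma$
(often quoted as "≈2.3× the STD"), converted to nm with the pixel size
along the cross-section direction.

**Interpolation choice.** Cross-sections are sampled with bicubic
(Keys, $a=-0.5$) interpolation rather than bilinear. Bilinear sampling
convolves the profile with a triangle kernel, which adds about
0.16 px² to the fitted variance — a +5% width bias for σ ≈ 1.2 px,
i.e. exactly the narrow widths sharp probes produce. Bicubic sampling
reproduces smooth profiles to much higher order and removes the bias;
`height_profile()` keeps plain bilinear, where sub-pixel smoothing is
irrelevant to the reported mean ± STD.

The apparent width of a filament is dominated by tip–sample
convolution: a blunter probe renders the same molecule wider. The
synthetic generator emulates this by the cross-section σ of the
rendered ridge; the package's probe-width comparison renders one
centerline at σ = 2.5 px and 1.2 px (≈5 nm vs ≈2 nm tip radius at
2 nm/px) and recovers both widths from the images.

## Skeleton contour length

Freehand tracing systematically overestimates contour length — a
hand-drawn, densely sampled polyline wiggles around the true backbone.
`skeletonize_molecule()` provides the unbiased alternative: threshold
the heights (the interactive "threshold intensity" slider), drop
components below `min_pixels`, and thin the support to a one-pixel
curve with the Zhang–Suen two-subiteration algorithm followed by a
sequential simple-point pruning pass. The pruning removes staircase
corners the parallel passes leave behind, so the final curve is a
*minimal* 8-connected chain; without it the chain metric double-counts
corners. Endpoints are never pruned and topology is preserved (loops
stay loops — relevant for circular plasmids).

`skeleton_length()` is the 8-connected chain metric: every adjacent
skeleton pixel pair counted once, lateral steps at the pixel size and
diagonal steps at $\sqrt{px^2+py^2}$; branched skeletons sum all
branches.

**Known bias.** The chain metric over a digitized curve carries a
positive bias that depends on the curve's orientation spectrum: a
digital straight line at angle θ measures
$\cos\theta + (\sqrt2 - 1)\sin\theta$ per unit length, up to +8% at
22.5° and ≈+4–5.5% averaged over orientations. On synthetic filaments
the package measures +4–6% against ground truth, of which ≈+4% is
already present in the chain length of the ideally digitized
centerline — it is a property of the estimator, not of the thinning.
A further ≈+1% comes from the thresholded support extending
$\sigma\sqrt{2\ln(A/t)}$ beyond the filament's true ends. The bias is
documented rather than corrected (no spline smoothing, no calibrated
step weights), because the tool's purpose is comparative morphometry;
users comparing against crystallographic lengths should expect the
skeleton to run a few percent long on smooth synthetic data, while on
real, finely wrinkled molecules resolution limits usually push the
estimate the other way. Freehand traces remain the larger estimate in
the package's tests (≈+9% with realistic oversampled jitter), so the
ordering freehand ≥ skeleton — the reason the skeleton tool exists —
is reproduced.

For reference, a B-form double helix has a 0.332 nm rise per base
pair, so a 2686 bp plasmid corresponds to
`bform_contour_nm(2686)` ≈ 892 nm.

## Angles and display

`measure_angle()` takes three points (arm, vertex, arm) and returns the
angle from the normalized dot product, computed in nm coordinates so
anisotropic pixels do not distort it; the result lies in 0–180°.
`upsample_for_display()` magnifies a map 10× by separable cubic
convolution over the 4×4 neighbourhood (Keys kernel, $a = -0.5$;
borders padded by linear extrapolation, so constants and linear ramps
are reproduced exactly). It is strictly cosmetic: all measurements use
the original grid.

## High-throughput mode

`detect_all()` applies the same detection pipeline to a whole image and
emits one record per particle: background-subtracted intensity sum,
solidity (pixel count over the rasterized convex hull), pixel size,
volume, and the same-second-moments ellipse (eccentricity, full major
and minor axis lengths in nm and their ratio). `batch_folder()` maps
this over a directory with one shared `threshold_factor`, skipping
unreadable files with a warning. `volume_histogram()` bins volumes (or
calibrated masses) over a user window — a mono-disperse preparation
shows a single mode. `calibrate_to_kda()` is the linear
volume-to-mass map through the origin against a standard such as
*E. coli* RNA polymerase (450 kDa).

## File dialects

* **NanoScope v5**: text header (`\*File list` … `\*File list end`) +
  16-bit little-endian frames; height = raw × Z-scale × Z-sensitivity
  / 2¹⁶, pixel size = scan size / pixel count. Other header versions
  are rejected, not guessed.
* **JPK TIFF**: two-page TIFF 6.0, page 1 a thumbnail; calibration
  `height = offset + multiplier × raw` from private IFD tags, with the
  two documented tag layouts (the channel-name tag shifts the doubles
  by one id between software generations) tried in order. The IFD walk
  is implemented in-package because no installed reader exposes
  private tags.
* **Igor binary wave v5** (Asylum): FP32/FP64 waves with per-axis
  deltas; for 3-D waves the first layer whose label contains "height"
  (case-insensitive) wins, else layer 0; m/µm/nm units converted.
* **ASCII x-y-z**: whitespace/comma tables, header lines auto-skipped
  (data starts at the first fully numeric row), grid completeness
  enforced.
* **Raster TIFF/JPEG/PNG**: convenience inputs with no physical
  calibration; both the nm-per-grey-level scale and the pixel size must
  be supplied explicitly, and RGB is collapsed to luminance with a
  warning.

Dispatch precedence in `load_any()` is hint > magic bytes > extension;
a TIFF carrying JPK tags routes to the JPK reader.

All coordinates exposed to users are 0-based (row, col) with half-open
crop ranges, matching raster storage order; row 0 is the top scan
line.

## The synthetic generator, and what passing tests mean

`make_blob()` renders $A e^{-r^2/2\sigma^2}$ with analytic volume
$2\pi\sigma^2 A \cdot$ pixel area; `make_filament()` renders a
Gaussian-profile ridge along a line, arc, or seeded smooth random walk
with exact centerline length as ground truth. Filament defaults are
anchored to reported DNA imaging values: backbone height 0.5 nm and
apparent FWHM 6.9 nm (σ ≈ 1.47 px at 2 nm/px). The walk turns by at
most 0.25 rad per 4 px step (curvature radius ≥ 16 px) and keeps a
self-separation of 8σ so the ridge never merges with itself;
self-intersecting attempts advance the seed deterministically and are
logged. `add_plane()` and `add_noise()` supply tilt and seeded Gaussian
noise for robustness tests.

These images emulate the *geometry* of SFM data, not its full physics:
no scan-line artefacts, no feedback ringing, no true tip dilation
(broadening is Gaussian by construction), no surface roughness.
Passing recovery tests therefore demonstrates that the measurement
chain is unbiased on known geometry at realistic scale — it does not
certify absolute accuracy on real scans, which inherit probe-shape and
deposition effects; that is what the volume-standard calibration is
for.

Problem sizes in the test-suite and acceptance runs are 160–512 px
images, 10–20 molecules per property — sizes at which every recovery
statistic is stable to well below its tolerance.

## Numerical choices, in one place

* Path resampling 1 px of arc; cross-sections ±`half_width_px` at
  0.25 px; at least 3 px half-width enforced.
* Gaussian fits via `minpack.lm::nls.lm` (the residual-function
  interface; the `nlsLM` model wrapper aborts on near-perfect synthetic
  data when constructing its model object at a zero-residual optimum).
* Automatic Sobel threshold 4×RMS; morphology 3×3 box elements.
* Tie-breaks: largest particle by area, then first in row-major scan.
* Quantization: NanoScope fixtures quantize at (Z-scale × Z-sens)/2¹⁶,
  JPK/TIFF/PNG at range/65535, JPEG is lossy (correlation, not
  equality, survives a round-trip), ASCII at 10 significant digits,
  IBW stores doubles exactly.
* Degenerate inputs fail loudly: empty masks, all-foreground
  backgrounds, empty skeleton supports, coincident angle points,
  incomplete ASCII grids, missing raster calibration.

## Limitations

Watershed splitting of touching particles, adaptive thresholding,
automated tracing, tip-deconvolution, and persistence-length statistics
are out of scope. The skeleton length bias discussed above is the one
systematic error a user is most likely to meet on clean data.
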