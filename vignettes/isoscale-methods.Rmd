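---
title: "Calibrating unequal X/Y scales in OCT B-scans with spherical beads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating unequal X/Y scales in OCT B-scans with spherical beads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoscale)
```

## The problem

A spectral-domain OCT B-scan is a lateral concatenation of axial A-scans.
The Y (depth) axis inherits the interferometric calibration of the A-scan
and is trustworthy; the X (lateral) axis is reconstructed by the device
software from scan geometry and normative assumptions, and in small eyes
(mouse imaging especially) its scale can differ from Y by a large factor.
On such an image every two-dimensional measurement is distorted: circles
display as ellipses, oblique distances are stretched, and oblique angles
are compressed toward the X axis. Only measurements exactly along X or Y
are straightforward.

`isoscale` does two things:

1. **Corrects measurements** made on an uncorrected scan, given the X/Y
   anisotropy factor `k` (the `geometry` and `image_correction` layers).
2. **Estimates `k`** from cross-sections of spherical fiducial beads of
   known physical diameter that appear in the scan (the `bead_fitting` and
   `calibration` layers), replacing manual rescaling against a circular
   template with a deterministic, quality-controlled fit.

## The distortion model

Let the displayed X scale exceed the Y scale by `k > 0` ("axis ratio"). A
physical circle of radius `r` then displays as the axis-aligned ellipse
`x^2/a^2 + y^2/b^2 = 1` with `b = r` (in Y-scale units) and `a = k b`. The
model is a pure anisotropic stretch of the X coordinate; it has no shear
and no rotation, which is why fitted bead orientations far from 0 degrees
are treated as a model-adequacy warning.

**Relative diameter.** The central chord of that ellipse whose endpoints
sit at polar angle `alpha` (measured from the X axis in the displayed
image) has half-length equal to the ellipse's polar radius,

    r(alpha) = a b / sqrt(b^2 cos^2 alpha + a^2 sin^2 alpha),

and dividing by `b` gives the dimensionless relative diameter

    d_r(alpha, k) = k / sqrt(cos^2 alpha + k^2 sin^2 alpha).

`d_r` runs from `k` at 0 degrees down to 1 at 90 degrees; a displayed
length measured along direction `alpha` divided by `d_r` is the true
length at the Y-axis scale. The package verifies this closed form against
a brute-force oracle that samples the ellipse boundary parametrically and
reads off the radius at each polar angle.

**Angle distortion.** The stretch maps a direction with true angle
`alpha_t` to the displayed angle `alpha_d` with
`tan(alpha_d) = tan(alpha_t)/k`. For the special case of a 45-degree
structure this is `alpha_d = arctan(b/a) = arctan(1/k)`. We adopt the
tangent law as the general form because it is the unique consequence of a
linear stretch of X: both axes are fixed points, the map is strictly
increasing on (0, 90) degrees, and it reproduces the 45-degree case. Its
inverse (`true_angle()`) restores, for example, vessel angles measured on
uncorrected scans. Angles are degrees in the public interface, measured
from the X (lateral) axis with period 180 degrees; radians are used only
internally.

## Bead detection and ellipse fitting

Spherical beads of known diameter (the package default is 154 um with a
+/- 5 um manufacturing tolerance, a size of dimensionally stable alginate
capsules used as intraocular fiducials) are genuinely circular in physical
space, so their displayed cross-section directly exhibits `k` as the ratio
of its fitted semi-axes `a/b`.

Segmentation is deliberately simple and deterministic:

1. Gaussian smoothing (`smooth_sigma`, default 1 px).
2. Global threshold — Otsu by default, fixed override available.
3. Connected components, with two filters: the bounding box must fit the
   user-supplied range of plausible displayed diameters, and components
   nested inside a larger component are dropped (a speckle-lit lumen
   otherwise labels as a second, spurious bead inside the capsule ring).
4. Subpixel boundary extraction by radial ray casting from the component
   centroid: along each of `n_rays` (default 120) rays the smoothed
   intensity is interpolated bilinearly and the boundary point is the
   half-maximum down-crossing nearest the outer rim of the component mask.
   Restricting the search to the mask rim means unrelated bright structure
   further along the ray — a retina-like band, a neighboring bead —
   cannot capture the edge. The half-maximum threshold is the midpoint of
   the image background (median outside all components) and the component's
   95th intensity percentile.

The boundary is then fitted with a direct least-squares conic constrained
to an ellipse (the numerically stable partitioned formulation of the
determinant constraint), followed by a Nelder–Mead geometric refinement of
the radial point-to-ellipse distance, run in data-centered coordinates so
that the whole procedure is exactly translation-equivariant. The algebraic
stage is closed-form and needs no initialization; the refinement matters
at larger boundary noise, where purely algebraic fits shrink the axes.
The reported residual is the RMS radial distance of the boundary points to
the fitted ellipse — exact along each center ray and a well-behaved proxy
for the orthogonal distance at bead-like eccentricities.

Axis convention: `a_px` is the semi-axis whose direction lies within 45
degrees of the image X axis and `b_px` the perpendicular one, so
`a_px/b_px` estimates `k` directly and fluctuates around 1 (not floored at
1) when the image is already isotropic — important when verifying that a
corrected image is actually corrected.

### Quality control

A bead enters the calibration only if its boundary is not truncated by the
image border (a clipped ellipse biases the ratio), has at least 20
boundary points, and the fit's RMS residual is at most `residual_threshold`
(default 0.75 px, about 1.5x the operating residual under the strongest
speckle the segmentation handles; values above it almost always indicate a
segmentation failure rather than a noisy but valid bead). Truncated beads
are excluded outright. A QC-passing fit with `|theta| > 10` degrees
warns, because the distortion model cannot produce rotated ellipses from
spheres.

## Calibration statistics

Per-bead ratios `a/b` are aggregated by their arithmetic mean with the
sample standard deviation (n-1) as dispersion — the mean-of-ratios rather
than ratio-of-means, matching how a per-bead factor with a +/- SD is
naturally reported; a median policy is available for outlier-prone data.
Two bead groups (e.g. subretinal vs epiretinal placement) are compared
with the classical equal-variance Student's t-test, two-sided, on the
per-bead ratios; Welch's test is available behind a flag. `pool_calibrations()`
mirrors the intended study design: groups are calibrated separately and
pooled only when the test finds no difference at the 0.05 level.
Zero-variance degenerate inputs are reported explicitly (equal means:
t = 0, p = 1; unequal: a `degenerate` flag) instead of erroring.

The known bead diameter `D` anchors absolute scales:
`y_um_per_px = D / mean(2 b_px)` and `x_um_per_px = y_um_per_px / k_mean`.
The +/- 5 um sphericity/manufacturing tolerance is recorded in the
calibration object but deliberately not propagated into `k_sd`: it is a
bound on a systematic property of the bead population, not a per-bead
sampling error, and the ratio `a/b` is in any case insensitive to the
bead's absolute size.

## Image correction

`rescale_image()` stretches the Y axis by `k` — the direction the physics
recommends, since it leaves the lateral sampling untouched — producing
`round(rows * k)` rows (half-away-from-zero). The exact unrounded `k` is
stored in the provenance and used for all measurement mathematics, so the
rounding never contaminates numbers. Interpolation is linear by default;
nearest preserves original intensities exactly, and cubic (natural spline
per column) is available but can overshoot at the bright capsule ring.
After correction both pixel scales equal `y_um_per_px / k`.

`measure_segment()` supports both routes and they agree by construction:
on a corrected image it is Euclidean pixel distance times the scale; on a
raw image with a calibration the displayed length is divided by
`d_r(alpha, k)` and converted through the axial scale, while the displayed
angle is mapped through `true_angle()`. On a raw image without a
calibration, oblique segments are refused with an explanation — there is
no way to correct them without `k`.

## The phantom generator

Validation runs entirely on seeded synthetic phantoms with exact ground
truth. The scene is specified in physical micrometers; the renderer maps
it to pixels through `y_um_per_px` and the single anisotropy source
`true_k` (`x_um_per_px = y_um_per_px / true_k`), so circles become
ellipses with exactly `a/b = true_k`. Beads render either as a bright
capsule wall with a dimmer cell-filled lumen ("ring", the typical
subretinal appearance) or as a uniformly bright blob ("disc", the typical
epiretinal appearance); both styles must — and do — calibrate to the same
`k`. Rendering uses 4x supersampling with box downsampling, which keeps
the aliasing error of the rendered edge well below the 0.2 px accuracy the
fit tests demand. Speckle is multiplicative log-normal,
`I * exp(N(0, sigma^2))` clipped to [0, 1], with `sigma = 0` reproducing
the clean render bit for bit. All randomness is drawn from an explicitly
specified generator (Mersenne-Twister, inversion normals) seeded from the
spec, and the caller's RNG state is restored afterwards.

Default study conditions (`sample_study()`): bead diameters from
N(154, (5/3)^2) um truncated at 3 SD — reading the quoted 154 +/- 5 um
manufacturing tolerance as a 3-sigma band — one bead per scan at a
randomized subpixel position, `y_um_per_px = 154/24` so a nominal bead
spans 24 rows, and `true_k = 3.35` as the canonical anisotropy of the
simulated instrument class.

### Numerical choices worth knowing about

* **Capsule wall thickness, 20 um.** The ring's outer edge must be a
  clean intensity step at the pixel scale of both axes for half-maximum
  edge localization to be unbiased. A much thinner wall makes the
  axial-direction profile a narrow blurred bump whose half-max crossing
  shifts outward, biasing `k` low by several tenths of a percent; 20 um
  (about 3 axial pixels at the default scale) removes the effect while
  remaining a plausible capsule membrane plus cell-layer thickness.
* **Speckle level, sigma = 0.6.** This is the strongest multiplicative
  speckle at which segmentation and QC remain reliable. It produces an
  end-to-end per-bead ratio scatter of roughly 0.5–1%. In-vivo per-bead
  scatter is several times larger; that excess comes from bead-level
  effects — tissue distortion, oblique sectioning of the bead by the scan
  plane, reader variability — which the phantom deliberately does not
  model. Passing phantom tests therefore demonstrates correctness of the
  estimation machinery, not the field dispersion of real recordings.
* **Pixel convention.** Pixel centers at integer coordinates, `x` =
  column, `y` = row, 1-based, row index increasing with depth. Output row
  `j` of a rescale samples input row `1 + (j-1)/k`.
* **Ties and degeneracies.** Circle fits have undefined orientation (any
  `theta` accepted); constant images segment to nothing rather than
  erroring; beads fully outside a phantom are a spec error while merely
  overlapping beads warn and annotate.

## Validation suite and problem sizes

The test suite validates, among other properties: agreement of the
closed-form `d_r` with the parametric chord oracle to 1e-6 over five axis
ratios on a 1-degree grid; the tangent angle law and its inverse to 1e-9
degrees; exact-ellipse recovery to 1e-6 and agreement with a brute-force
grid-search fit on 8-point instances; a 95%+ rate of 2%-accurate ratio
recovery under 0.5 px boundary jitter (500 trials); end-to-end factor
recovery with |bias| < 1% and seed-to-seed SD < 3% for true
`k` in {1.5, 2.5, 3.35, 5} (50 seeded studies of 20 beads each);
restoration of circular beads (ratio within 1% of 1) after rescaling
clean renders by the self-estimated calibration — clean, because two
independent noisy detection passes plus the group estimate's own error
would add ~1% scatter that belongs to the recovery property, not the
resampling machinery being checked; 0.5% agreement between the raw-plus-
correction and rescale-then-measure routes over random segments; and
Student's-t behavior on same-truth groups (p > 0.05 in at least 90% of
trials, near-uniform p distribution, Kolmogorov–Smirnov distance < 0.1
over 1000 trials at 10 beads per group). `scripts/acceptance.R` recomputes
the same quantities from scratch at slightly reduced replication (25
seeds per recovery condition, 500 group-comparison trials) and writes
them to JSON.

## Known limitations

* The model is a pure axis-aligned stretch: no shear, no rotation, no
  field-dependent (optical) distortion, no refraction correction. Fitted
  orientations far from zero flag exactly this.
* Z (volume) handling is out of scope; the package treats a B-scan in
  isolation.
* The phantom does not simulate depth-dependent attenuation, shadowing,
  PSF anisotropy, or real OCT speckle statistics; see above for what that
  implies about transferring phantom accuracy numbers to real data.
* A calibration transfers only within the same instrument configuration
  and population; cross-device variation is documented but not modeled.
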