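---
title: "Methods: 3D spindle reconstruction and tracking from sparse z-stacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D spindle reconstruction and tracking from sparse z-stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, numerical choices and known
limitations behind `spindletrack`, in the spirit of a methods section: what
is computed, under which assumptions, and what the bundled tests do and do
not demonstrate.

## Problem setting and assumptions

The package targets time-lapse movies of metaphase cells acquired with very
few z-slices per time point — the reference regime is 21 frames at
3-minute intervals, three slices with a 2 µm gap, pixel size
0.04–0.07 µm — with a brightfield cortex channel and a fluorescently
labelled spindle channel. Two structural assumptions drive everything
else:

* the **cell cortex** is well approximated by an ellipsoid (mitotic cells
  round up; measured in-plane eccentricities center near 0.3, so an
  ellipsoid is kept rather than a sphere);
* the **spindle** is well approximated by an ellipsoid whose longest axis
  joins the two poles, with length > width ≥ height.

All physical coordinates use the convention: x = column index ×
pixel size, y = row index × pixel size (0-based indices), z = slice index
× z-step. Axis order in arrays is `[T, Z, Y, X]`.

## Cortex reconstruction from 3 slices

Each z-slice of the cortex mask contributes a closed boundary. Two
reconstructions are implemented (`fit_cortex_ellipsoid()`):

* **Profile fit (default).** An enclosing ellipse is fitted per slice; the
  squared in-plane radii follow
  $A(z)^2 = A_{eq}^2\bigl(1 - ((z - z_0)/c)^2\bigr)$ for an ellipsoidal
  cell, a quadratic in $z$ whose coefficients give the axial center $z_0$,
  the axial semi-axis $c$ and the equatorial axes. With three or more
  planes this is exact up to mask discretisation; when the quadratic is
  degenerate (all slices on one side of the equator, or dominated by
  noise) the fit falls back to a spherical axial prior
  ($c$ = mean in-plane radius).
* **Joint MVEE.** All boundary pixels, lifted to their slice z, are fed to
  the minimum-volume enclosing ellipsoid. This is kept as an explicit
  option (`method = "mvee"`), but it is *not* the default for a geometric
  reason worth recording: the minimum-volume ellipsoid through three
  near-equatorial rings is strongly disc-flattened — the axial semi-axis
  collapses toward the slice span and, to keep covering the outer rings,
  the in-plane axes inflate (≈ 19% for the default geometry). Ray-traced
  pole-cortex distances computed against such a fit are systematically too
  long by tens of percent. The profile fit uses exactly the same inputs
  but exploits the ellipsoid assumption instead of volume minimality,
  and recovers the generating ellipsoid to ≈ 1% in the bundled synthetic
  tests.

## Spindle reconstruction via PSF axial inversion

The imaging PSF is modelled as a separable Gaussian: a 2D lateral Gaussian
with independent widths $\sigma_x \ne \sigma_y$ (pixels) and a 1D axial
Gaussian with width $\sigma_z$ (µm). `fit_psf_gaussians()` calibrates
these from a bead z-stack (Levenberg–Marquardt, `minpack.lm`); the
amplitude is corrected for the offset between the brightest pixel and the
continuous lateral center. `simulate_psf()` provides both the Gaussian
model (default, with the standard widefield approximations
$\sigma_{xy} = 0.21\,\lambda/\mathrm{NA}$,
$\sigma_z = 0.66\,\lambda n_i/\mathrm{NA}^2$) and a scalar Gibson–Lanni
diffraction integral for users who want a physically richer stack; the
Gaussian path is the one consumed downstream, because its axial profile is
exactly the model inverted next.

For each frame the brightest masked slice of the spindle channel is used.
Intensities inside the mask are normalised to the retained maximum (the
reference intensity is defined as the maximum over the retained pixels of
the current frame), the top 30% brightest pixels are kept (exactly
$\lceil 0.3\,n \rceil$ of $n$ mask pixels; ties broken by pixel order),
and each pixel is mapped to $\hat z = \sigma_z \sqrt{-\log I} + z_c$. Two
facts about this inversion are intentional:

* it is the exact inverse of $I = \exp(-((z - z_c)/\sigma)^2)$ on
  $[z_c, \infty)$, to machine precision (this is asserted on a $10^4$
  point grid);
* the sign of the axial offset is not observable from a single intensity.
  The non-negative branch is returned and the ambiguity recorded; the
  enclosing-ellipsoid fit of a symmetric structure is insensitive to the
  global choice, and the in-plane pole geometry — which carries the
  tracking readouts — is unaffected.

The resulting point cloud is fitted with the MVEE to give the spindle
ellipsoid; its principal axes define the pole/width/height endpoints.

## Minimum-volume enclosing ellipsoid

`fit_mvee()` implements Khachiyan's barycentric coordinate ascent on the
dual D-optimal design problem, accelerated with Wolfe–Atwood away steps,
inside a core-set outer loop: the fit runs on the extreme points along a
fixed direction set, violators are pulled in, and the loop repeats until
every point satisfies $(p-c)^\top M (p-c) \le 1 + \varepsilon$
(default tolerance $10^{-4}$; the stopping rule is tightened by
$d/(d{+}1)$ so this lab-frame bound holds). Because the optimal ellipsoid
touches at most $d(d+3)/2 = 9$ points, the working subsets stay tiny and
fits on multi-thousand-point clouds take milliseconds. Degenerate
(coplanar/collinear) inputs raise a rank error naming the deficient
dimension rather than returning an unbounded fit.

The test suite cross-checks fitted volumes against an algorithmically
independent convex solver — a primal log-barrier interior-point method on
minimise $-\log\det A$ subject to $\|A p_i + b\| \le 1$, with analytic
gradient and Hessian — agreeing to better than $10^{-5}$ relative volume
over hundreds of random clouds.

## Pole refinement

Enclosing-ellipsoid poles are biased along the long axis, so
`refine_poles()` samples the max-projected spindle mask along the full
pole-axis line at half-pixel steps (nearest-pixel lookup) and snaps the
poles to the first and last foreground crossings. Sampling the *full*
line, not just the segment between the initial poles, makes refinement
symmetric: an overshooting estimate — the common case that motivates the
step — strictly shrinks onto the mask, and an undershooting one (which
arises when the brightness-core point cloud under-spans the spindle)
extends to the same mask boundary. The refined z follows the 3D axis
line, and the ellipsoid is rebuilt with the refined half-length (centroid
re-centred on the refined poles). Frames whose axis misses the mask
entirely are excluded and logged, never clamped.

## Six-point identity tracking

For each endpoint pair (poles, width, height) independently, the 2×2
distance matrix between current and previous endpoints decides the
labelling: the crossed pairing is adopted exactly when it has the smaller
summed squared displacement, which for the symmetric endpoint pairs
produced by an ellipsoid fit coincides with the per-axis global
minimum-displacement labelling (verified against exhaustive enumeration
over all $2^{T-1}$ labelings for short movies). Ties keep the previous
labels. Distances are 3D in micrometres, so the anisotropic z enters
naturally.

Because the raw per-frame labels come from a deterministic, memoryless
sign convention on the ellipsoid orientation, a swap, once needed, is
needed at every subsequent frame; the correction log therefore records
*parity changes* — one event per actual identity flip (for example, the
long axis rotating through 90° produces exactly one logged correction at
the crossing frame), while the applied relabelling propagates silently.

## Kinematics

Frame-to-frame rotation is $R = A_t A_{t-1}^\top$, where the columns of
$A$ are the unit length/width/height directions, projected back to the
nearest proper rotation to shed rounding. Euler angles use the
$R = R_z(\gamma)R_y(\beta)R_x(\alpha)$ convention with standard
right-handed factors; extraction is defined by exact round-trip
consistency with this composition (recomposition reproduces $R$ to
$10^{-9}$ away from gimbal lock). At gimbal lock
($|\cos\beta| < 10^{-9}$) only $\alpha \mp \gamma$ is determined; the
convention sets $\gamma = 0$, folds the free angle into $\alpha$, and
flags the frame.

Displacement decomposition projects the centroid displacement (pole
reference points are available by option) onto the previous frame's unit
axes; the fractions $|\Delta|/\|\Delta\|$ satisfy
$f_{lg}^2 + f_{eq}^2 + f_{ax}^2 = 1$ identically for nonzero motion, with
a zero-motion flag otherwise. Rates are reported per frame interval with
an optional per-minute normalisation; summaries include medians of the
absolute angle series, an inverse-ECDF probe (nearest-rank convention,
default percentile 0.75), and cumulative rotation series. Division of
displacements by the cortex semi-axis, as a cell-size normalisation, is
deliberately left to downstream analysis.

## Classical segmentation pipelines

Three conventional pipelines are provided for label generation.
Parameters the upstream description leaves open are fixed as defaults and
config-exposed:

* **Chromosomes** (`segment_chromosomes()`): median filter → Otsu →
  8-connected border clearing → Savitzky–Golay boundary smoothing
  (window 15, order 3, applied to the closed boundary as two periodic 1D
  signals) → scanline refill. The smoothing window necessarily rounds
  sharp corners by a few pixels, which the tests account for.
* **Dye-labelled spindles** (`segment_spindle_threshold()`): median
  filter → adaptive local-mean threshold (block 51 px, offset 0.02 on the
  normalised scale) → one 3×3-disc dilation and erosion → convex hull of
  all retained foreground (joining the two half-spindles) → smoothing →
  direct least-squares ellipse fit.
* **Inverse snake** (`segment_spindle_snake()`): Gaussian smoothing,
  gradient-magnitude edge map, and an active contour seeded on the
  chromosome-plate boundary that propagates *outward* along radial
  normals with a speed that vanishes where the edge response exceeds a
  fraction (default 0.6) of its maximum, under implicit
  elasticity/rigidity regularisation. The contour stops slightly inside a
  heavily blurred boundary (about one blur width); orientation, the
  readout that matters for perpendicularity checks, is recovered to a few
  degrees. Contours that shrink below the seed area raise a convergence
  error.

Classical candidates carry score 1.0 so the same conditional filtering
(score, area window, border margin) applies to scored and unscored masks
alike; centroid linking is single-object nearest-neighbour with
score-then-index tie-breaks and gap carry-forward.

The ellipse primitive is the direct least-squares conic fit with the
ellipse constraint $4ac - b^2 = 1$ (numerically stabilised partitioned
form, with input centering/scaling); eccentricity is
$\sqrt{1 - B^2/A^2}$.

## The synthetic movie generator

`generate_movie()` renders the reference acquisition regime with known
per-frame pose: cortex as a dark ring at the ellipsoid's slice
cross-section on a gray background, spindle as a $(1 - r^2)$ radial
falloff inside the spindle ellipsoid (blurred laterally with the
rendering PSF), chromosome plate as a thin disc perpendicular to the long
axis, plus additive Gaussian noise and an optional illumination ramp.
Defaults: 21 frames, 3 slices, 2 µm z-gap, 3-minute interval, 512 px at
0.06887 µm/px, cortex semi-axes (9.5, 9.0, 8.6) µm (in-plane eccentricity
0.32), spindle semi-axes (5.5, 3.5, 2.75) µm. Noise is drawn from a
per-frame seed derived from the master seed, so renders are
order-independent and the whole movie is a pure function of its
parameters. Ground-truth endpoints follow the continuous scripted
rotation, so truth labels never jump at sign-convention boundaries; truth
distances come from the same analytic ray tracer applied to the true
ellipsoids (asserted to $10^{-9}$ internal consistency).

The $(1-r^2)$ photometric profile is a fixture convention, chosen so the
top-30% intensity filter retains a central core as in real spindles. Two
consequences are worth knowing. First, the core cloud *under*-spans the
spindle, so pole refinement against the mask does real work in this
direction too (see above). Second, the width/height readouts reflect the
bright core rather than the mask outline — in the bundled synthetic runs
the measured width is therefore smaller than the scripted mask width,
while the refined length matches the scripted length to about a pixel.
What passing tests show is that the geometry chain is correct under the
stated assumptions; they do not show robustness to photometric effects
the renderer omits (photobleaching curves, depth-dependent aberrations,
camera noise beyond additive Gaussian).

## Study conditions used by the bundled checks

The end-to-end recovery check uses the default regime with a scripted
rotation of 5°/frame about z starting at −50° (so the long axis never
crosses ±90° and label parity stays interpretable frame by frame) and an
in-plane drift of (0.06, 0.04) µm/frame — about 1.2 µm over the hour, a
realistic metaphase displacement that keeps both poles well clear of the
cortex. Under these conditions the pipeline recovers the per-interval
rotation with median error below 1°, and pole-cortex distances with
median relative error ≈ 1%; the worst single frame is bounded by the
≈ 1-pixel quantisation of the refined pole (0.069 µm on a ≈ 3 µm
distance ≈ 2%). Problem sizes in the tests (200 random clouds for the
MVEE oracle, 1000 random lines for ray tracing, 1000 Euler triples, 100
simulated tracking movies, one full-resolution synthetic movie) were
chosen to exercise the estimators thoroughly while keeping a full test
run in a few minutes on one CPU.

## Known limitations

* Everything rests on the ellipsoid approximations; severely bent or
  barrel-shaped spindles, or blebbing cortices, violate them.
* The axial inversion uses a single slice per frame and one global
  $\sigma_z$; depth-dependent PSF broadening is not modelled.
* The width and height axes of the spindle are not refined against the
  mask (only the poles are), and with one-sided axial offsets the height
  axis is weakly constrained — length-axis readouts are the reliable
  ones.
* Multi-spindle scenes and anaphase are out of scope; the tracker follows
  a single object.
* Statistical comparison between experimental conditions is downstream of
  this package and intentionally not included.
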