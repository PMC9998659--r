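# spindletrack

3D reconstruction and tracking of the mitotic spindle and cell cortex from
sparse z-stack time-lapse microscopy.

Live-cell assays of spindle positioning typically acquire only a handful of
z-slices per time point (three slices 2 µm apart, one stack every 3 minutes
is a common regime) to limit phototoxicity. Recovering 3D spindle motion
from such data requires modelling, not just measurement. `spindletrack`
implements the non-learned computational core of that workflow for cell
biologists quantifying spindle movements in metaphase cells: it takes
per-frame segmentation masks (from any source — classical pipelines are
included, or masks exported from a learned segmenter) plus the raw
fluorescent channel, and produces identity-consistent 3D pole trajectories,
pole-to-cortex distances, and a decomposition of spindle motion into
interpretable rotation and translation components.

## The model

**Cortex.** The mitotic cell boundary is modelled as an ellipsoid
(mitotic cells are round but not perfectly spherical; typical in-plane
eccentricity ≈ 0.3). Each z-slice of the cortex mask contributes its
boundary; the default reconstruction fits an enclosing ellipse per slice
and solves the quadratic axial profile
`A(z)² = A_eq² (1 − ((z − z₀)/c)²)` for the axial center and semi-axis,
which is exact for an ellipsoidal cell sampled on ≥ 3 planes. A joint
minimum-volume enclosing ellipsoid (MVEE) over all lifted boundary pixels
is available as an alternative.

**Spindle.** Pixel intensities inside the spindle mask are converted to
axial positions by inverting the Gaussian axial profile of the imaging
point-spread function: with intensity normalised to the in-mask reference
peak, `ẑ = σ_z √(−log I) + z_c`. The brightest 30% of mask pixels become a
3D point cloud, and the spindle ellipsoid is its MVEE (Khachiyan
barycentric ascent with Wolfe–Atwood away steps and a core-set outer
loop). The six principal-axis endpoints define the spindle length
(pole-to-pole), width, and height axes.

**Pole refinement.** The enclosing-ellipsoid pole estimate is biased along
the long axis, so poles are refined by scanning the max-projected spindle
mask along the pole-axis line and snapping each pole to the first/last
foreground crossing.

**Ray tracing.** Pole-to-cortex distances come from the analytic
intersection of the pole-to-pole line with the cortex ellipsoid: in the
ellipsoid's principal frame the line substitutes into the surface equation
to give `χt² + γt + ζ = 0`, classified by its discriminant (0, 1 or 2
intersections), with no iterative search.

**Identity tracking.** Each of the three endpoint pairs is matched to the
previous frame through its 2×2 Euclidean distance matrix (six-point
tracking); crossed pairings that reduce total displacement are swapped and
logged, and corrections propagate until the next event.

**Kinematics.** Frame-to-frame motion is summarised by the rotation matrix
`R = A_t A_{t−1}ᵀ` between axis triads, factorised as
`R = R_z(γ) R_y(β) R_x(α)` — α tumbling, β rolling, γ rotation — and by the
displacement of the centroid projected on the previous frame's axes:
longitudinal Δlg, equatorial Δeq, axial Δax, with fractions satisfying
`f_lg² + f_eq² + f_ax² = 1`.

Also included: classical chromosome/spindle segmentation (Otsu pipeline,
adaptive-threshold + convex-hull pipeline, inverse active contour seeded on
the metaphase plate), Stage-3 style candidate filtering and centroid
linking, evaluation metrics (IoU, average precision, pixelwise mask
correlation, spindle–plate perpendicularity), intensity-aware padding, and
a ground-truth synthetic movie generator that renders the full acquisition
regime so every stage is testable without data downloads.

## Worked example

```r
library(spindletrack)

# a scripted ground-truth movie: 21 frames, 3 z-slices 2 um apart,
# 3-minute intervals, spindle rotating 5 deg/frame about z with a slow
# in-plane drift
p <- sim_params(initial_angles_deg = c(0, 0, -50),
                angle_increments_deg = c(0, 0, 5),
                centroid_velocity_um = c(0.06, 0.04, 0),
                seed = 42)
sim <- generate_movie(p)

tr <- track_pipeline(sim$movie, sim$masks$spindle, sim$masks$cortex)
tr
#> Tracked spindle: 21 accepted frame(s), 0 excluded, 2 identity correction(s)
#>   spindle length 10.92-11.02 um; pole-cortex distances 2.33-5.05 um

summary(tr)
#> Spindle kinematics over 20 intervals (deg/3 min)
#>   median |alpha| 0.158  |beta| 0.102  |gamma| 4.976
#>   median fractions: f_lg 0.737  f_eq 0.675  f_ax 0.008
#>   median displacement 0.089 um per interval
```

The spindle length readout (~11 µm) and per-interval rotation
(`median |gamma|` ≈ 5°/3 min) recover the scripted ground truth; the
pole-cortex distances shrink on one side as the scripted drift carries the
spindle toward the cortex. `write_tracks(tr, "track.csv")` exports the
full per-frame table (endpoints, distances, Euler angles, displacement
components, correction flags).

A command-line interface wrapping the same functions is installed at
`inst/cli/spindletrack.R` with subcommands `simulate`, `annotate`, `track`,
`psf-fit` and `evaluate`.

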