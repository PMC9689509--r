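---
title: "Stereovision girth measurement: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereovision girth measurement: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stereogirth)
```

## The measurement model

A subject wears tights printed with a black/white checkerboard (2.5 cm
between adjacent corners along the body surface) and stands on a turntable
in front of a calibrated stereo rig at shooting distance `D`.  Four stereo
pairs are captured at turntable angles 0/90/180/270°.  Every checkerboard
corner is a physical landmark roughly four pixels in footprint, so corner
correspondence localizes features one to two orders of magnitude more
precisely than blob-like colour markers, and a single corner row
reconstructed in 3-D traces the body cross-section whose arc length is the
girth.

The pipeline assumes:

* a **pinhole rig without lens distortion** — calibration (intrinsics,
  relative pose, `D`) is an input, read from a YAML file
  (`read_calibration()`); distortion correction, if needed, must happen
  upstream;
* a **rigid, vertical-axis turntable** whose axis is known (exact in
  simulation; axis estimation from data is out of scope);
* **locally row-ordered corners**: within the marker rectangle the corners
  of one row project with strictly increasing x in both views, which holds
  whenever the rectangle spans less than half the circumference and the
  surface is convex;
* a **near-convex cross-section** varying slowly along the body axis, so
  the plane normal to the axis at the mean point height is a meaningful
  measurement plane.

## Stage parameters, defaults and why

### Colour classification (`hsv_ranges()`, `classify_hsv()`)

H ∈ [0,180], S,V ∈ [0,255] — the 8-bit machine-vision convention the
calibrated thresholds are expressed in.  Red owns two hue intervals
(0–10 and 156–180) around the hue wrap; cyan is 78–99; black is any pixel
with V < 46 (value dominates); white needs V ≥ 221 and S < 30.  Bounds are
half-open `[min, max)` except at the scale tops, which are closed so pure
white (V = 255) and wrap-around red stay classifiable.  Two published
inconsistencies are resolved as: red `Smin` = 45 (the tabulated value;
the accompanying prose says "greater than 43") and white `Vmax` = 255 (the
printed 225 is taken as a transposition; both bounds are configurable,
`hsv_ranges(white_v_max = 225)` restores the printed value).

### Corner detection (`detector_params()`)

* `quality = 0.05` — candidates must reach 5 % of the strongest response;
  checkerboard corners are far stronger than any texture response, so the
  threshold only suppresses noise.
* `min_distance = 5` px — non-maximum-suppression radius, about half the
  checkerboard pixel step of the default rig (≈ 11.5 px), so at most one
  detection per physical corner.
* structure tensor: 5×5 box window over central-difference gradients of
  the σ = 1 px Gaussian-smoothed image.
* sub-pixel refinement: Gaussian-weighted gradient-orthogonality
  iteration, `eps = 1e-3` px, `max_iter = 40`, window half-width 5
  (an 11×11 window).  A literal 5×5 window is supported
  (`refine_window = 2`) but at this pixel scale it leaves rasterization
  noise unaveraged (measured RMS 0.51 px vs 0.20 px on the default
  synthetic scene); 11×11 still keeps neighbouring corners (≥ 11 px away)
  outside the weight mass.
* inside `run_algorithm1()` the marker footprints are excluded from the
  candidate set (markers interrupt the checkerboard, so responses on their
  boundaries are not grid corners), and the non-maximum test runs on the
  full response surface so an excluded maximum cannot promote spurious
  neighbours.

### Multi-line matching

`nstep(D)` evaluates the rig calibration `7.02 D² − 45.18 D + 93.43` and
rounds to the nearest pixel (the published operating point D = 2.4 m
gives 25 px from a raw value of 25.43, fixing the rounding convention).
The polynomial's validity range is not stated with it; the package warns
outside 1.5–3.0 m, a documented guess covering close-range anthropometric
rigs.  The synthetic sessions use their own exact step
`f_y · interval / D` since their camera differs from the calibrated one.

### Girth fitting (`fit_girth()`)

The closed-curve method named for this stage is defined in prior work the
package does not reimplement; `fit_girth()` is a documented stand-in
behind a stable interface.  Points are projected onto the plane normal to
the body axis at their mean height, ordered by azimuth, and least-squares
fitted with a truncated Fourier series (default `smooth_harmonics = 5`)
in the intermediate arc parameter (cumulative chord length, the classic
device for fitting closed curves that are not single-valued functions of
the polar angle); the smoothed samples are joined by a periodic
piecewise-cubic curve whose arc length is evaluated densely (4000
samples).  The low-pass stage matters: an interpolating spline converts
per-corner triangulation noise into a systematic circumference
overestimate (about +2 cm at 0.3–0.5 px disparity error on the synthetic
rig), while a least-squares fit — in the spirit of polynomial curve
fitting — suppresses it.  On exact circle/ellipse samples the fit is
accurate to < 0.002 cm, and doubling point density changes the result by
< 0.01 %.

`select_measurement()` applies the garment-standard rules verbatim:
maximum of three lines for bust/hip/thigh, minimum for waist, and for
under-bust/mid-thigh the single line shifted down two steps from the
bust/thigh baseline.

## The segmentation architecture and its accounting

`build_backbone()`/`build_pspnet()` describe the network symbolically —
stem 7×7/64 stride-2 convolution, 3×3 stride-2 max-pool, bottleneck stages
of 3/4/23/3 blocks, pyramid pooling at grid sizes 1/2/3/6 — and
`count_parameters()`/`count_flops()` walk the description in closed form,
so the accounting is exact and instant.  Decisions the published totals do
not pin down, resolved here:

* **group count g = 2** for every bottleneck 3×3 convolution.  The
  worked illustration of grouping shows g = 4 on one 64-channel block, but
  only g = 2 applied everywhere reproduces the printed totals (32.52 M
  parameters); both are supported (`backbone_config(groups = …)`).
* **attention reduction r = 16, bias-free shared perceptron** — the value
  consistent with the printed parameter total; not otherwise stated.
* **stride placement** on the bottleneck's 3×3 convolution (the common
  v1.5 layout), which reproduces the standard 42.50 M / ≈7.8 GMac
  accounting of the 101-layer backbone without its classification head.
* **FLOP convention**: 1 multiply–accumulate = 1 FLOP, convolution and
  linear layers only.  Under this convention the totals are 7.80 B and
  5.89 B; the printed 7.84/5.94 imply a slightly different (unstated)
  convention — counting normalization at two operations per element plus
  residual additions lands on 7.84 — but the package reports the stated
  convention rather than reverse-engineering one.
* the pyramid head uses bilinear upsampling and batch norm after each
  convolution; no auxiliary loss (not mentioned for this use).

Because the 15,795-image training corpus is not deposited, full-scale
segmentation accuracy is a non-goal.  What the package verifies instead is
that the architecture *as wired* is differentiable and learnable:
`build_tiny_segnet()` assembles the same ingredients (grouped 3×3
convolution, CBAM, pyramid pooling with bilinear upsampling, per-pixel
classifier) at width 8, with exact hand-derived backpropagation
(finite-difference-checked in the test suite), and reaches ≥ 90 % MIOU on
held-out procedural silhouette fixtures within 60 Adam steps.  Passing
this says nothing about human-image segmentation accuracy; it certifies
the wiring, the gradients and the metric implementations.

## What the simulator emulates — and what it does not

`generate_measurement_session()` renders an elliptic cylinder (default
aspect 0.8) whose checkerboard is laid out by **surface arc length**, so
adjacent corners are exactly one 2.5 cm interval apart along the
circumference — the premise behind the pixel-step relation.  The default
cross-section perimeter is 75 cm = 30 intervals, matching the four-marker
layout with horizontal spacings (8, 7, 8, 7): markers sit at cell centres
(half-interval offsets), red and cyan alternating, vertical offsets
(−1, +1, −1, +1), so each view sees exactly one red and one cyan marker
and the four view rectangles tile all 30 corner columns exactly once.
For other circumferences the spacings are configurable (the 100 cm
sessions in the tests use 40 intervals with spacings 10/10/10/10;
near-equal spacings keep rectangle edges away from the visibility limb).
The default rig is slightly verged (optical axes converging at `D`),
320×240 px, f = 1100 px, 0.3 m baseline, D = 2.4 m — chosen so one
checkerboard interval spans ≈ 11.5 px, comfortably above the detector's
suppression radius while keeping rendering fast; renders are supersampled
3× to approximate a uniform pixel-aperture PSF (at 2× the point-sampled
renderer's rasterization bias dominates corner localization).

Not emulated: cloth wrinkles and pose deformation, lighting and shading
gradients, lens distortion, chromatic effects, segmentation errors (the
simulator provides exact masks), and non-convex cross-sections.
Consequently the synthetic recovery results certify the *geometry and
matching chain* — calibration-consistent triangulation, de-rotation,
curve fitting — under pixel noise, and nothing about garment drape or
real segmentation quality.  The noise model is i.i.d. Gaussian on the
8-bit scale (σ configurable; tests use σ ∈ {0, 1, 2}).

## Numerical and interface decisions

* **Coordinates**: 0-based pixel indices at pixel centres, x right,
  y down; right-handed 3-D frames; metres internally, centimetres in all
  reports.
* **Triangulation**: midpoint of the common perpendicular of the two
  back-projected rays — symmetric, rectification-free; rays closer than
  1e-6 rad to parallel raise a degenerate-geometry error.
* **Strict rectangle bounds**: corners exactly on a marker-centroid
  coordinate are excluded (the constraint uses strict inequalities);
  x-ties are broken by ascending y only to make the ordering total.
* **Unequal constrained counts** raise a diagnostic error (per-view
  counts, rectangle bounds) rather than truncating — the method defines
  no recovery rule, and silent truncation would desynchronise the rank
  pairing.
* **Problem sizes in the test suite**: sessions at 320×240 with 75 cm and
  100 cm girths; 20 matching sessions across noise levels; 10-seed
  Monte-Carlo recovery at σ = 1; learnability on 64 fixtures of 64×64 px.
  These sizes make the full suite run in minutes while leaving every
  stage's acceptance margin measurable.

## Known limitations

* The closed-curve stage is a surrogate for the original (externally
  defined) polynomial fitting method; the interface (`fit_girth()`)
  isolates it so an exact reimplementation can be slotted in.
* The full-scale network is symbolic; forward execution is implemented
  for the reduced variant only — parameter/FLOP accounting and shape
  inference are exact for the full architecture, but no pretrained
  weights exist or are claimed.
* Marker blobs closer than about one pixel to a corner column (very wide
  rectangles seen at grazing azimuth) can shadow that column's corner;
  the default layouts keep a safe margin.
* `nstep()` extrapolates outside 1.5–3.0 m with a warning; the quadratic
  has a minimum near D ≈ 3.2 m and must not be used beyond it.
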