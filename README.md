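# stereogirth

Binocular-stereovision anthropometry: measuring human body circumferences
(bust, under-bust, waist, hip, thigh, mid-thigh) from calibrated stereo
image pairs of a subject wearing a checkerboard-patterned suit on a
turntable.

## The measurement problem

Girth measurement with a single stereo rig and a turntable proceeds in
three stages:

1. **Segmentation** of the girth region.  The package implements the
   attention-augmented pyramid-pooling architecture used for this step —
   CBAM blocks (channel attention
   `A_CF = σ(MLP(AvgPool F) ⊕ MLP(MaxPool F))` followed by spatial
   attention `A_SF = σ(f₇ₓ₇[AvgPool F_C ; MaxPool F_C])`) after each stage
   of a ResNet101 backbone whose bottleneck 3×3 convolutions are grouped
   (`P₂ = h·w·(D_in/g)·(D_out/g)·g = P₁/g`) — with exact trainable-parameter
   and FLOP accounting, the PA/MPA/MIOU quality metrics, and a reduced-depth
   trainable variant (pure R backpropagation) for end-to-end verification.
2. **Stereo matching** of checkerboard corners.  Shi–Tomasi
   minimum-eigenvalue detection with sub-pixel refinement; red/cyan marker
   extraction by HSV thresholds and centroiding; a regional constraint that
   keeps only corners strictly inside the axis-aligned rectangle spanned by
   the two marker centroids; and rank pairing of the x-ordered constrained
   sets.  Additional measurement lines come from shifting the marker
   baseline by the pixel step of one checkerboard interval,
   `N_step(D) = round(7.02 D² − 45.18 D + 93.43)` for the calibrated rig
   (25 px at the working distance D = 2.4 m).
3. **Girth fitting.**  Matched pairs are triangulated (midpoint of the
   common perpendicular), reverse-rotated by each view's turntable angle
   into one body frame, merged across views, and fitted with a smooth
   closed curve in an intermediate arc parameter whose length is the girth.
   The final measurement takes the maximum of three lines for bust/hip/
   thigh, the minimum for waist, and the single line two steps down for
   under-bust/mid-thigh; series are compared by mean absolute difference
   (MAD).

Because no measurement dataset is deposited with the method, the package
ships a synthetic stereo-scene simulator — an analytic ray-traced,
checkerboard-textured elliptic cylinder with the four-marker layout
(horizontal spacings 8, 7, 8, 7 intervals; vertical offsets −1, +1, −1, +1)
on a turntable — that provides exact ground truth for every stage, so the
whole pipeline is testable end to end.

## Worked example

```r
library(stereogirth)

# architecture accounting for the segmentation backbone
architecture_report()
#> Backbone accounting (input 224x224, 1 MAC = 1 FLOP, conv + linear):
#>            backbone params_million flops_billion param_reduction_pct flop_reduction_pct
#>           ResNet101          42.50          7.80                  NA                 NA
#>  Improved ResNet101          32.52          5.89                23.5               24.4

# synthetic turntable session: 75 cm elliptic waist, 4 stereo pairs
sc  <- build_scene(default_config())
ses <- generate_measurement_session(sc$model, sc$layout, sc$rig, seed = 1)
ses
#> <measurement_session: 4 views at 0/90/180/270 deg, girth 75.00 cm, noise sigma 0.0>

measure_session(ses, "waist")
#> Girth measurement (waist)
#>   per-line (cm): 74.73, 74.67, 74.96
#>   final: 74.67 cm  [truth 75.00 cm, |error| 0.33 cm]
```

The three per-line girths are the circumferences of the corner rows one
step above, on, and one step below the marker baseline; the waist rule
selects the minimum.  The 0.33 cm recovery error (0.4 %) is well inside
the ±2.0 cm garment-standard tolerance the measurement is certified
against.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/stereogirth-tool.R count-params
Rscript inst/scripts/stereogirth-tool.R measure --part waist
Rscript inst/scripts/stereogirth-tool.R match --left L.png --right R.png
```

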