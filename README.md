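# fishstereo

Non-contact measurement of fish body length from underwater binocular
stereo keypoints, with correction for the secondary refraction introduced
by a flat-port waterproof housing.

## The problem

Monitoring growth in aquaculture needs body-length measurements without
netting and handling the fish. A calibrated stereo camera pair can do
this: detect anatomical keypoints on each fish in both views, triangulate
them, and take the Euclidean distance between snout and tail,

```
L = sqrt((X_H - X_T)^2 + (Y_H - Y_T)^2 + (Z_H - Z_T)^2).
```

But a camera in a waterproof housing sees the scene through a flat glass
port, and light bends twice on its way in — water→glass, then glass→air.
The in-air calibration no longer describes the geometry: underwater image
coordinates are magnified radially (increasingly toward the image edge),
and lengths triangulated from raw pixels are biased.

`fishstereo` implements the coordinate-level fix. With the port at the
camera's external focal point, the underwater image coordinate `x_r` and
the coordinate `x_a` of the *equivalent air image* are linked through the
water-side incidence angle `α`:

```
x_r = T·tan(asin(n_r·sin α / n_g)) + (d − T)·tan(asin(n_r·sin α / n_a))
x_a = T·tan(asin(n_a·sin α / n_g)) + (d − T)·tan α
```

(`d` port distance, `T` glass thickness, `n_a, n_g, n_r` the indices of
air, glass, water). Both are strictly monotone in `α`, so the correction
solves one for `α` by bracketed root finding and evaluates the other.
Simpler single-interface and more general tilted-port variants are
included, along with Zhang's planar checkerboard calibration, COCO-style
keypoint annotation I/O, evaluation metrics (NME, AP over IoU thresholds,
relative error / MRPE), and a synthetic refractive scene simulator used
as the ground-truth oracle for the whole pipeline.

For whom: anyone building or validating an underwater stereo
morphometrics rig — the package takes detector output (keypoint JSON) and
calibration as input; it does not include the detector itself.

## Worked example

Simulate a small tank scene (ground truth known), then measure it:

```r
library(fishstereo)

scene <- simulate_fish_scene(3, seed = 7, z_range_mm = c(450, 550))
measure_scene(scene, model = "parallel")
#>   fish_id length_mm true_length_mm       re_pct
#> 1       1 104.72273      104.72273 1.328501e-11
#> 2       2  91.47759       91.47759 4.147790e-11
#> 3       3 104.64343      104.64343 3.583832e-11
```

Noise-free observations come back to the true length at machine
precision — the forward refraction used in rendering and the inverse used
in correction are exact inverses, and triangulation is exact on
consistent pixels. With detector-like noise (σ = 0.5 px) on a 13-fish
cohort, correction roughly halves the error of the uncorrected pipeline:

```r
noisy <- simulate_fish_scene(13, noise_sigma_px = 0.5, seed = 11,
                             z_range_mm = c(450, 550))
c(corrected   = mean(measure_scene(noisy, model = "parallel")$re_pct),
  uncorrected = mean(measure_scene(noisy, model = "none")$re_pct))
#>   corrected uncorrected
#>   0.3177837   0.4279312
```

Those numbers are mean relative errors in percent. A single fish in
detail:

```r
m <- measure_fish(scene$observations$left[[1]],
                  scene$observations$right[[1]], scene$rig)
m
#> fish_measurement: length 104.723 mm (9 keypoints triangulated)
round(m$points3d, 2)
#>                  X      Y      Z
#> mouth       -12.95 -22.98 476.18
#> eye          -2.64 -21.26 476.57
#> ...
```

Coordinates are mm in the left-camera frame; the length is the distance
from the mouth point to the midpoint of the two tail-fin landmarks
(`tail_rule = "midpoint"`, configurable).

File-based use mirrors this: `write_scene()` exports COCO-dialect
keypoint JSON plus a rig YAML, and `run_measurement()` (or the
`inst/cli/fishstereo.R` command-line wrapper with subcommands `simulate`,
`calibrate`, `correct`, `measure`, `evaluate`) consumes them and writes a
measurement CSV and error-statistics JSON.

See `vignettes/underwater-length-measurement.Rmd` for the models, their
assumptions, parameter meanings and the design decisions.

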