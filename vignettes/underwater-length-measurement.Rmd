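---
title: "Refraction-corrected stereo measurement of fish body length"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refraction-corrected stereo measurement of fish body length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishstereo)
```

## The measurement problem

Measuring the body length of farmed fish without netting and handling them
is a standard need in aquaculture. A cheap solution is a calibrated
binocular camera pair in a waterproof housing: detect anatomical keypoints
on each fish in both views, triangulate them, and take the Euclidean
distance between the snout and the tail,

$$L = \sqrt{(X_H - X_T)^2 + (Y_H - Y_T)^2 + (Z_H - Z_T)^2}.$$

The catch is refraction. Light from an underwater target crosses two
interfaces before reaching the lens — water to the flat glass port, then
glass to the air inside the housing — and bends at both. An in-air stereo
calibration therefore no longer describes the geometry: underwater image
coordinates are magnified radially, increasingly so away from the image
center (a pincushion-like distortion), and lengths triangulated from raw
underwater pixels are biased. `fishstereo` implements the coordinate-level
fix: map each detected keypoint from the underwater image to the position
it would have had in the *equivalent air image*, then run ordinary stereo
triangulation on the corrected coordinates.

## The refraction models

All three models describe a 1-D mapping between the underwater image
coordinate $x_r$ and the equivalent-air coordinate $x_a$, parameterized by
the water-side incidence angle $\alpha$ and the port geometry: distance
$d$ from the external focal point to the enclosure, glass thickness $T$,
and refractive indices $n_a, n_g, n_r$ of air, glass and water.

* **single** — ignores the glass slab entirely; one bend at a water–air
  interface placed at the external focal point:
  $x_a = d\tan\big(\arcsin(n_a \sin(\arctan(x_r/d))/n_r)\big)$. Closed
  form in both directions.
* **parallel** — the full secondary-refraction model for a glass plane
  parallel to the camera plane:
  $$x_r = T\tan\big(\arcsin(n_r\sin\alpha/n_g)\big) +
  (d-T)\tan\big(\arcsin(n_r\sin\alpha/n_a)\big),$$
  $$x_a = T\tan\big(\arcsin(n_a\sin\alpha/n_g)\big) + (d-T)\tan\alpha.$$
  Both are strictly increasing in $\alpha$, so conversion solves one
  equation for $\alpha$ by bracketed root finding and evaluates the other.
* **tilted** — generalizes the parallel model to a glass plane tilted by
  $\beta$ relative to the camera plane, with $d - T/\cos\beta$ replacing
  the slab offset and $\tan(\cdot - \beta)$ terms. At $\beta = 0$ it
  reduces exactly to the parallel model.

Placing the interface at the external focal point ($d = f$, the default
in `default_flat_port()`) is what makes the mapping depth-independent, so
a single underwater image determines its equivalent air image without
knowing the target range. The small-angle limit of the magnification
$x_r/x_a$ is the index ratio $n_r/n_a$ (1.33 for water against air), and
the ratio grows with the incidence angle; keeping the slab in the model
(parallel vs single) lowers the predicted magnification at every angle,
which is exactly the difference between correcting with and without
secondary refraction.

```{r}
port <- flat_port(d_mm = 3, T_mm = 2.8, n_air = 1, n_glass = 1.6,
                  n_water = 1.33)
magnification_ratio(c(0.01, 0.3, 0.6), port, "single")
magnification_ratio(c(0.01, 0.3, 0.6), port, "parallel")
```

### Numerical choices

The conversions solve strictly monotone 1-D equations on the incidence
angle with `stats::uniroot` (Brent's method) at tolerance `1e-12`, on the
bracket $[0, \alpha_{TIR})$ where
$\alpha_{TIR} = \arcsin(n_a/n_r)$ is the water-side angle beyond which no
transmitted ray exists (total internal reflection). Coordinates beyond
the attainable range raise a `fishstereo_beyond_tir` condition;
`correct_keypoints()` converts that into a visibility-0 flag on the
affected keypoint rather than failing the fish. The rotationally
symmetric models are applied to the radial coordinate about the principal
point (azimuth preserved); the tilted model is derived in one direction
only, so it is applied along the tilt-plane axis with the orthogonal axis
handled by the parallel map. A consequence of that per-axis convention is
that at $\beta = 0$ the keypoint-level tilted path applies the parallel
map componentwise rather than radially; the 1-D maps themselves coincide
exactly.

## Camera model and calibration

Cameras follow the standard pinhole model with intrinsic matrix

$$A = \begin{bmatrix} \alpha & \gamma & u_0 \\ 0 & \beta & v_0 \\
0 & 0 & 1\end{bmatrix}, \qquad \alpha = f/dx,\ \beta = f/dy,$$

an optional two-term radial distortion $(k_1, k_2)$ applied in normalized
coordinates (inverted by fixed-point iteration, at most 20 steps), and
pose $p_c = Rp_w + t$. Pixel coordinates are 0-based, x right, y down.
Skew $\gamma$ is carried but defaults to zero.

Calibration is the planar-target (checkerboard) method: a DLT homography
per view (with Hartley normalization for conditioning), the two
absolute-conic constraints per homography
($h_1^T B h_2 = 0$, $h_1^T B h_1 = h_2^T B h_2$) stacked and solved by
SVD — at least three distinct poses are required — followed by closed-form
recovery of $A$ and per-view decomposition into $(R, t)$ with an SVD
projection to the nearest rotation. By default `calibrate_camera()` then
polishes all parameters jointly by Gauss–Newton on the total squared
reprojection error. This refinement step is part of the method as
conventionally practiced, and it is what makes the reported residuals
track the corner noise: the purely linear decomposition leaves residuals
roughly twice the injected noise because the orthonormalization of the
rotation columns is not a least-squares fit to the pixels. `refine =
FALSE` gives the linear-only estimate. Planar views determine only the
five pixel-unit intrinsics; the physical focal length `f_mm` is a gauge
supplied by the user (it cancels in every projection, and only sets the
mm scale of the metric image plane and the default port distance).

## The synthetic scene generator

Because a real tank experiment (live fish, trained detector, private
images) cannot ship with a package, `fishstereo` carries a simulator that
serves as the oracle for every downstream module. Its defaults emulate
the tank experiment the method was designed for, and were fixed once at
design time:

* rig: 3 mm lenses, 3 µm pixels, 640×480, principal point (320, 240),
  baseline 60 mm with parallel optical axes (the baseline and relative
  pose are assumptions — realistic for a compact housing — since no
  measured values are available);
* ports: glass thickness 2.8 mm at the focal point, indices
  1 / 1.6 / 1.33;
* fish: body lengths drawn from 80–105 mm, placed 300–700 mm in front of
  the rig (the tank's working depth is about 500 mm); nine landmarks
  placed by a fixed anatomical template, seeded jitter of at most 2% of
  the length, an optional spine bend, and a rigid pose — rescaled about
  the mouth so the mouth-to-tail-fin-midpoint distance equals the nominal
  length exactly;
* observations: the pinhole ("equivalent air") projection pushed through
  the forward refraction map, plus isotropic Gaussian pixel noise
  (default σ = 0.5 px) standing in for detector error, since no detector
  noise model is available.

What the simulator does *not* emulate: photorealistic appearance,
occlusion between fish, detector failure modes that are correlated
across keypoints or views, curved-glass or dome ports, and turbidity.
Passing tests therefore demonstrate the geometric correctness of the
correction–triangulation pipeline under the stated noise model, not
detector robustness on real imagery.

## End-to-end behavior

A noise-free scene is recovered to machine precision — the master oracle:
render a fish through the forward refraction map, correct the
observations, triangulate, and the true length comes back to better than
one part in $10^6$:

```{r}
scene <- simulate_fish_scene(3, seed = 7, z_range_mm = c(450, 550))
measure_scene(scene, model = "parallel")
```

Skipping the correction on the same observations (`model = "none"`,
triangulating raw underwater pixels through the in-air calibration)
inflates the error. The bias is partially self-cancelling — the inflated
disparity shrinks the estimated range, which compensates most of the
transverse magnification — so what remains is the *nonlinear* part of the
radial magnification, a few tenths of a percent to a few percent
depending on where the fish sits in the field. On noisy 13-fish cohorts
(the cohort size of the original tank experiment, which reports MRPE over
13 fish) the corrected pipeline beats the uncorrected one essentially
always; per-fish noise makes single-fish comparisons flip occasionally,
which is why the cohort, not the individual fish, is the unit of
comparison:

```{r}
noisy <- simulate_fish_scene(13, noise_sigma_px = 0.5, seed = 11,
                             z_range_mm = c(450, 550))
c(corrected = mean(measure_scene(noisy, model = "parallel")$re_pct),
  uncorrected = mean(measure_scene(noisy, model = "none")$re_pct))
```

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `d_mm` | `f_mm` | mm | focal point to enclosure; `d = f` enables single-image equivalence |
| `T_mm` | 2.8 | mm | port glass thickness |
| `n_air, n_glass, n_water` | 1, 1.6, 1.33 | — | refractive indices |
| `tilt_rad` | 0 | rad | camera-plane vs glass-plane angle |
| `model` | `"parallel"` | — | `single`, `parallel`, `tilted`, or `none` |
| `tail_rule` | `"midpoint"` | — | tail point: midpoint of the two tail-fin landmarks, or either one |
| `noise_sigma_px` | 0.5 | px | simulated detector noise |

The tail rule deserves a note: the measurement is defined between the
snout and "the tail", but the keypoint schema has two tail-fin landmarks
(top and bottom of the fin) and no single tail point. The midpoint of the
two is the default because it is symmetric, stable under fin motion, and
reduces to either fin when one is occluded only by explicit choice.

## Degenerate inputs and error conditions

All errors are classed conditions (`fishstereo_*`), so callers can react
per keypoint or per fish: points at or behind a camera
(`behind_camera`), total internal reflection (`beyond_tir`), collinear or
insufficient calibration targets (`degenerate_configuration`,
`insufficient_views`), (near-)parallel triangulation rays
(`degenerate_geometry`, rays closer than $10^{-8}$ rad), a missing
required keypoint (`missing_keypoint`), a zero NME normalizer, and an
empty length list. Triangulation uses QR on the stacked 4×3 system rather
than normal equations, for conditioning; the test suite checks it against
an independent closed-form two-ray midpoint solution.

## Problem sizes used in the checks

The shipped test suite and the acceptance script run entirely on
synthetic data at these sizes, chosen to exercise the estimators well
while keeping a full run in the tens of seconds: $10^4$ random
coordinates per refraction model for the inverse-pair property, $10^3$
random stereo scenes for triangulation, 100 noise-free single-fish scenes
for the master oracle, 100 noisy 13-fish cohorts for the corrected vs
uncorrected comparison, and 4–5 checkerboard views of 48 corners for
calibration.

## Known limitations

* The tilted model is 1-D by derivation; a full 2-D ray trace through a
  tilted slab is out of scope, and the per-axis application is an
  approximation whose error grows with $\beta$.
* One glass slab only: no dome ports, no multi-layer windows, no
  wavelength dependence.
* The correction is exact only when the interface sits at the external
  focal point ($d = f$); the `d_mm` parameter admits other geometries but
  then the equivalent-air mapping is itself an approximation that ignores
  the target-range dependence.
* Body length is the straight snout-to-tail chord; strongly curved fish
  are underestimated by construction (centerline methods are a different
  tool).
* Calibration assumes detected checkerboard corners are given; corner
  detection from images is not included.
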