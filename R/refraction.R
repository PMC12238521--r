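#' Flat-port refraction geometry
#'
#' Describes a camera sealed behind a plane-parallel glass window ("flat
#' port"): `d_mm` is the distance from the camera's external focal point to
#' the enclosure, `T_mm` the glass thickness, and the three refractive
#' indices describe air (inside the housing), glass, and water. `tilt_rad`
#' is the angle between the camera plane and the glass plane for the
#' non-parallel model.
#'
#' A ray from an underwater target bends twice before reaching the lens:
#' water to glass, then glass to air ("secondary refraction"). The models in
#' this package map the underwater image coordinate \eqn{x_r} to the
#' coordinate \eqn{x_a} the same camera would have recorded with no
#' water/glass in the path (the "equivalent air image"), and back.
#'
#' @param d_mm distance from external focal point to the enclosure, mm;
#'   defaults to the interface-at-focal-point geometry when built via
#'   [default_flat_port()]. Must satisfy `d_mm >= T_mm`.
#' @param T_mm glass thickness, mm (>= 0).
#' @param n_air,n_glass,n_water refractive indices (all >= 1, and
#'   `n_water < n_glass` in the regime modeled here).
#' @param tilt_rad camera-plane vs glass-plane angle in radians,
#'   `0 <= tilt_rad < pi/2`.
#' @return An object of class `flat_port`.
#' @export
flat_port <- function(d_mm, T_mm, n_air = 1.0, n_glass = 1.6,
                      n_water = 1.33, tilt_rad = 0) {
  fs_assert(is.finite(d_mm) && is.finite(T_mm) && d_mm >= T_mm && T_mm >= 0,
            "need d_mm >= T_mm >= 0")
  fs_assert(n_air >= 1 && n_glass >= 1 && n_water >= 1, "refractive indices must be >= 1")
  fs_assert(n_water < n_glass, "model assumes n_water < n_glass")
  fs_assert(tilt_rad >= 0 && tilt_rad < pi / 2, "tilt must lie in [0, pi/2)")
  structure(list(d_mm = d_mm, T_mm = T_mm, n_air = n_air, n_glass = n_glass,
                 n_water = n_water, tilt_rad = tilt_rad),
            class = "flat_port")
}

#' @export
print.flat_port <- function(x, ...) {
  cat(sprintf("flat_port: d=%g mm, T=%g mm, n=(%g, %g, %g), tilt=%g deg\n",
              x$d_mm, x$T_mm, x$n_air, x$n_glass, x$n_water,
              rad2deg(x$tilt_rad)))
  invisible(x)
}

#' Default flat port with the interface at the focal point
#'
#' The single-image equivalence between underwater and air images requires
#' the air-water interface to sit at the camera's external focal point, so
#' the port distance defaults to the focal length.
#'
#' @param K a [camera_intrinsics()] object supplying the focal length.
#' @param T_mm glass thickness in mm (default 2.8).
#' @param ... further arguments passed to [flat_port()].
#' @return A `flat_port` with `d_mm = K$f_mm`.
#' @export
default_flat_port <- function(K, T_mm = 2.8, ...) {
  flat_port(d_mm = K$f_mm, T_mm = T_mm, ...)
}

#' Snell's law refraction
#'
#' @param theta_in incidence angle(s) from the surface normal, radians, in
#'   `[0, pi/2)`.
#' @param n_from,n_to refractive indices of the incident and transmitting
#'   media.
#' @return Refracted angle(s) in radians.
#' @export
snell_refract <- function(theta_in, n_from, n_to) {
  fs_assert(all(theta_in >= 0 & theta_in < pi / 2),
            "incidence angle must lie in [0, pi/2)")
  arg <- n_from * sin(theta_in) / n_to
  if (any(arg > 1))
    fs_stop("total internal reflection: no transmitted ray",
            "fishstereo_tir")
  asin(arg)
}

# critical water-side incidence angle: beyond it the water->air refracted
# ray does not exist
alpha_tir <- function(port) asin(port$n_air / port$n_water)

# ---- 1-D coordinate maps, parameterized by the water-side incidence angle ----

# single-interface model: underwater coordinate at water-side angle a_r
x_r_single <- function(port, a_r) port$d_mm * tan(a_r)

# parallel system: underwater image coordinate as a function of the
# water-side incidence angle alpha
x_r_parallel <- function(port, alpha) {
  with(port, T_mm * tan(asin(n_water * sin(alpha) / n_glass)) +
         (d_mm - T_mm) * tan(asin(n_water * sin(alpha) / n_air)))
}

# parallel system: equivalent-air image coordinate at the same alpha
x_a_parallel <- function(port, alpha) {
  with(port, T_mm * tan(asin(n_air * sin(alpha) / n_glass)) +
         (d_mm - T_mm) * tan(alpha))
}

# non-parallel (tilted) system counterparts
x_r_tilted <- function(port, alpha) {
  with(port, {
    T_mm * (tan(asin(n_water * sin(alpha) / n_glass)) - tan(tilt_rad)) +
      (d_mm - T_mm / cos(tilt_rad)) *
        tan(asin(n_water * sin(alpha) / n_air) - tilt_rad)
  })
}

x_a_tilted <- function(port, alpha) {
  with(port, {
    T_mm * (tan(asin(n_air * sin(alpha) / n_glass)) - tan(tilt_rad)) +
      (d_mm - T_mm / cos(tilt_rad)) * tan(alpha - tilt_rad)
  })
}

# solve f(alpha) = target on [lower, upper] by safeguarded bracketed root
# finding; f must be strictly increasing on the bracket
solve_alpha <- function(f, target, lower, upper, what = "coordinate") {
  fl <- f(lower) - target
  fu <- f(upper) - target
  if (fl > 0 || fu < 0)
    fs_stop(sprintf("%s outside the attainable (TIR-limited) range", what),
            "fishstereo_beyond_tir")
  if (fl == 0) return(lower)
  if (fu == 0) return(upper)
  stats::uniroot(function(a) f(a) - target, lower = lower, upper = upper,
                 f.lower = fl, f.upper = fu, tol = 1e-12)$root
}

BRACKET_EPS <- 1e-9

#' Single-refraction correction (underwater to equivalent air)
#'
#' Closed-form map ignoring the glass slab: the ray bends once at a
#' water-air interface placed at the external focal point,
#' \deqn{x_a = d \tan(\arcsin(n_a \sin(\arctan(x_r/d)) / n_r)).}
#' Odd in `x_r`; for small coordinates \eqn{x_a \to x_r\, n_a/n_r}.
#'
#' @param x_r underwater image coordinate(s), mm.
#' @param port a [flat_port()].
#' @return Equivalent-air coordinate(s) `x_a`, mm.
#' @export
correct_single <- function(x_r, port) {
  stopifnot(inherits(port, "flat_port"))
  with(port, d_mm * tan(asin(n_air * sin(atan(x_r / d_mm)) / n_water)))
}

#' Single-refraction forward map (air to underwater)
#'
#' Exact inverse of [correct_single()]: given the equivalent-air coordinate,
#' returns where the underwater scene images the same ray.
#'
#' @param x_a equivalent-air image coordinate(s), mm.
#' @param port a [flat_port()].
#' @return Underwater coordinate(s) `x_r`, mm.
#' @export
observe_single <- function(x_a, port) {
  stopifnot(inherits(port, "flat_port"))
  arg <- port$n_water * sin(atan(x_a / port$d_mm)) / port$n_air
  if (any(abs(arg) > 1))
    fs_stop("air-side coordinate beyond the TIR-limited range",
            "fishstereo_beyond_tir")
  port$d_mm * tan(asin(arg))
}

#' Parallel-system secondary-refraction maps
#'
#' The parallel model traces the ray water -> glass -> air through a slab of
#' thickness `T` parallel to the camera plane. Both the underwater
#' coordinate \eqn{x_r} and the equivalent-air coordinate \eqn{x_a} are
#' strictly increasing functions of the water-side incidence angle
#' \eqn{\alpha}; the conversion solves one for \eqn{\alpha} by bracketed
#' root finding (tolerance 1e-12) and evaluates the other.
#' `correct_parallel` maps underwater to air; `observe_parallel` is its
#' exact inverse. Both are odd and vectorized.
#'
#' @param x_r,x_a image coordinate(s) in mm.
#' @param port a [flat_port()].
#' @return The converted coordinate(s), mm.
#' @export
correct_parallel <- function(x_r, port) {
  stopifnot(inherits(port, "flat_port"))
  vapply(x_r, function(x) {
    if (x == 0) return(0)
    a <- solve_alpha(function(al) x_r_parallel(port, al), abs(x),
                     0, alpha_tir(port) - BRACKET_EPS,
                     "underwater coordinate")
    sign(x) * x_a_parallel(port, a)
  }, numeric(1))
}

#' @rdname correct_parallel
#' @export
observe_parallel <- function(x_a, port) {
  stopifnot(inherits(port, "flat_port"))
  vapply(x_a, function(x) {
    if (x == 0) return(0)
    a <- solve_alpha(function(al) x_a_parallel(port, al), abs(x),
                     0, alpha_tir(port) - BRACKET_EPS,
                     "air-side coordinate")
    sign(x) * x_r_parallel(port, a)
  }, numeric(1))
}

#' Tilted (non-parallel) system secondary-refraction maps
#'
#' Generalize the parallel model to a glass plane tilted by angle `tilt_rad`
#' relative to the camera plane. With zero tilt both maps reduce exactly to
#' the parallel ones. The maps are not odd when the tilt is nonzero, so the
#' root search runs over a symmetric bracket in the incidence angle.
#' Requires `d > T / cos(tilt)`.
#'
#' @param x_r,x_a image coordinate(s) along the tilt axis, mm.
#' @param port a [flat_port()] with the desired `tilt_rad`.
#' @return The converted coordinate(s), mm.
#' @export
correct_tilted <- function(x_r, port) {
  stopifnot(inherits(port, "flat_port"))
  check_tilt_geometry(port)
  br <- tilted_bracket(port)
  vapply(x_r, function(x) {
    a <- solve_alpha(function(al) x_r_tilted(port, al), x,
                     br[1], br[2], "underwater coordinate")
    x_a_tilted(port, a)
  }, numeric(1))
}

# incidence-angle bracket on which both Eq. maps are defined and strictly
# increasing: the water-side TIR bound above, and below it the angle where
# the refracted ray grazes the tilted glass plane
tilted_bracket <- function(port) {
  lo <- asin(-port$n_air * cos(port$tilt_rad) / port$n_water)
  c(lo + BRACKET_EPS, alpha_tir(port) - BRACKET_EPS)
}

#' @rdname correct_tilted
#' @export
observe_tilted <- function(x_a, port) {
  stopifnot(inherits(port, "flat_port"))
  check_tilt_geometry(port)
  br <- tilted_bracket(port)
  vapply(x_a, function(x) {
    a <- solve_alpha(function(al) x_a_tilted(port, al), x,
                     br[1], br[2], "air-side coordinate")
    x_r_tilted(port, a)
  }, numeric(1))
}

check_tilt_geometry <- function(port) {
  if (port$d_mm <= port$T_mm / cos(port$tilt_rad))
    fs_stop("invalid geometry: requires d > T / cos(tilt)",
            "fishstereo_geometry")
  invisible(TRUE)
}

#' Refractive magnification ratio
#'
#' Ratio of the underwater to the equivalent-air image coordinate,
#' \eqn{x_r(\alpha) / x_a(\alpha)}, as a function of the water-side
#' incidence angle. For the single-interface model this is
#' \eqn{\tan(\arcsin(n_r \sin\alpha / n_a)) / \tan\alpha}; its small-angle
#' limit is the index ratio \eqn{n_r / n_a}. The ratio grows with the
#' incidence angle (pincushion distortion); the parallel model, which keeps
#' the glass slab, yields a smaller ratio than the single-interface model at
#' the same angle.
#'
#' @param alpha water-side incidence angle(s), radians, in `(0, alpha_TIR)`.
#' @param port a [flat_port()].
#' @param model one of `"single"`, `"parallel"`, `"tilted"`.
#' @return Magnification ratio(s) `x_r / x_a` (dimensionless).
#' @export
magnification_ratio <- function(alpha, port, model = c("single", "parallel", "tilted")) {
  stopifnot(inherits(port, "flat_port"))
  model <- match.arg(model)
  atir <- alpha_tir(port)
  fs_assert(all(alpha > 0 & alpha < atir),
            "alpha must lie in (0, alpha_TIR)")
  switch(model,
    single = {
      with(port, tan(asin(n_water * sin(alpha) / n_air)) / tan(alpha))
    },
    parallel = x_r_parallel(port, alpha) / x_a_parallel(port, alpha),
    tilted = x_r_tilted(port, alpha) / x_a_tilted(port, alpha))
}

# dispatch table for the 1-D maps
refraction_map <- function(model, direction = c("correct", "observe")) {
  direction <- match.arg(direction)
  fs_assert(model %in% c("single", "parallel", "tilted"),
            "model must be one of single, parallel, tilted")
  switch(paste(model, direction, sep = "_"),
    single_correct = correct_single,
    single_observe = observe_single,
    parallel_correct = correct_parallel,
    parallel_observe = observe_parallel,
    tilted_correct = correct_tilted,
    tilted_observe = observe_tilted)
}

# apply a 1-D refraction map to a metric image point (mm). The rotationally
# symmetric models act on the radius about the principal axis (azimuth
# preserved); the tilted model acts on the tilt-plane axis (x) with the
# orthogonal axis handled by the parallel map componentwise.
apply_refraction_metric <- function(m, port, model, direction) {
  if (model == "tilted") {
    fx <- refraction_map("tilted", direction)
    fy <- refraction_map("parallel", direction)
    c(fx(m[1], port), fy(m[2], port))
  } else {
    f <- refraction_map(model, direction)
    r <- sqrt(m[1]^2 + m[2]^2)
    if (r == 0) return(m)
    m * (f(r, port) / r)
  }
}

#' Refraction-correct detected keypoints
#'
#' Maps each visible keypoint from the underwater image to its equivalent
#' air-image position: pixel to metric image coordinates (undistorting),
#' radial application of the chosen model's underwater-to-air map, then back
#' to pixels. Invisible keypoints pass through unchanged; a keypoint whose
#' radius falls beyond the TIR-limited range is marked invisible in the
#' output.
#'
#' @param kps a [fish_keypoints()] object (pixel coordinates).
#' @param K a [camera_intrinsics()] object.
#' @param port a [flat_port()].
#' @param model refraction model: `"single"`, `"parallel"`, or `"tilted"`.
#' @return A [fish_keypoints()] object with corrected pixel coordinates.
#' @export
correct_keypoints <- function(kps, K, port, model = "parallel") {
  stopifnot(inherits(kps, "fish_keypoints"), inherits(K, "camera_intrinsics"),
            inherits(port, "flat_port"))
  pts <- kps$points
  for (i in seq_len(nrow(pts))) {
    if (pts[i, "visibility"] == 0) next
    m <- pixel_to_metric(pts[i, c("u", "v")], K)
    ok <- tryCatch({
      ma <- apply_refraction_metric(m, port, model, "correct")
      pts[i, c("u", "v")] <- metric_to_pixel(ma, K)
      TRUE
    }, fishstereo_beyond_tir = function(e) FALSE)
    if (!ok) pts[i, "visibility"] <- 0
  }
  fish_keypoints(pts, bbox = kps$bbox)
}
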