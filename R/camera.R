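#' Pinhole camera intrinsics
#'
#' Container for the internal parameters of a pinhole camera: focal length
#' \eqn{f} (mm), pixel pitches \eqn{dx, dy} (mm/px), skew \eqn{\gamma} (px),
#' principal point \eqn{(u_0, v_0)} (px) and a two-term radial distortion
#' \eqn{(k_1, k_2)} applied in normalized image coordinates. The intrinsic
#' matrix is
#' \deqn{A = \begin{bmatrix} \alpha & \gamma & u_0 \\ 0 & \beta & v_0 \\
#'   0 & 0 & 1 \end{bmatrix}, \quad \alpha = f/dx,\ \beta = f/dy.}
#'
#' Pixel coordinates are 0-based, x to the right, y downward, origin at the
#' top-left corner; the principal point lives in the same frame. Lengths are
#' millimetres throughout.
#'
#' @param f_mm focal length in mm (> 0).
#' @param dx_mm,dy_mm pixel pitch in mm per pixel (> 0).
#' @param skew skew coefficient \eqn{\gamma} in px (default 0).
#' @param u0,v0 principal point in px.
#' @param k1,k2 radial distortion coefficients (dimensionless, default 0).
#' @return An object of class `camera_intrinsics`.
#' @seealso [intrinsic_matrix()], [camera_to_pixel()], [pixel_to_metric()]
#' @export
camera_intrinsics <- function(f_mm, dx_mm, dy_mm, skew = 0, u0, v0,
                              k1 = 0, k2 = 0) {
  fs_assert(is.numeric(f_mm) && f_mm > 0, "f_mm must be > 0")
  fs_assert(dx_mm > 0 && dy_mm > 0, "pixel pitches must be > 0")
  fs_assert(all(is.finite(c(f_mm, dx_mm, dy_mm, skew, u0, v0, k1, k2))),
            "intrinsic parameters must be finite")
  structure(list(f_mm = f_mm, dx_mm = dx_mm, dy_mm = dy_mm, skew = skew,
                 u0 = u0, v0 = v0, k1 = k1, k2 = k2),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf(
    "camera_intrinsics: f=%g mm, pitch=(%g,%g) mm/px, pp=(%g,%g) px, skew=%g, k=(%g,%g)\n",
    x$f_mm, x$dx_mm, x$dy_mm, x$u0, x$v0, x$skew, x$k1, x$k2))
  invisible(x)
}

#' Intrinsic parameter matrix A
#'
#' @param K a [camera_intrinsics()] object.
#' @return 3x3 upper-triangular matrix with positive diagonal.
#' @export
intrinsic_matrix <- function(K) {
  stopifnot(inherits(K, "camera_intrinsics"))
  matrix(c(K$f_mm / K$dx_mm, K$skew, K$u0,
           0, K$f_mm / K$dy_mm, K$v0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Camera pose (extrinsics)
#'
#' Rotation `R` and translation `t` mapping world coordinates into the camera
#' frame: \eqn{p_c = R p_w + t}.
#'
#' @param R 3x3 rotation matrix (orthonormal, det +1, checked to 1e-9).
#' @param t length-3 translation vector in mm.
#' @return An object of class `camera_extrinsics`.
#' @export
camera_extrinsics <- function(R = diag(3), t = c(0, 0, 0)) {
  R <- as.matrix(R)
  t <- as.numeric(t)
  fs_assert(is_rotation(R), "R must be a proper rotation matrix (R'R = I, det = +1)")
  fs_assert(length(t) == 3L && all(is.finite(t)), "t must be a finite 3-vector")
  structure(list(R = R, t = t), class = "camera_extrinsics")
}

#' @export
print.camera_extrinsics <- function(x, ...) {
  cat("camera_extrinsics: t =", format(x$t), "mm\n")
  print(x$R)
  invisible(x)
}

#' World-to-camera coordinate change
#'
#' Applies the rigid transform \eqn{p_c = R p_w + t}.
#'
#' @param p length-3 world point (mm) or an n x 3 matrix of points.
#' @param ext a [camera_extrinsics()] object.
#' @return Point(s) in the camera frame, same shape as `p`.
#' @export
world_to_camera <- function(p, ext) {
  stopifnot(inherits(ext, "camera_extrinsics"))
  if (is.matrix(p)) {
    fs_assert(ncol(p) == 3L, "point matrix must be n x 3")
    t(ext$R %*% t(p) + ext$t)
  } else {
    fs_assert(length(p) == 3L, "point must have 3 coordinates")
    as.numeric(ext$R %*% p + ext$t)
  }
}

# distortion in normalized coordinates: xd = xn * (1 + k1 r^2 + k2 r^4)
distort_normalized <- function(xn, yn, K) {
  r2 <- xn^2 + yn^2
  s <- 1 + K$k1 * r2 + K$k2 * r2^2
  list(x = xn * s, y = yn * s)
}

# inverse by fixed-point iteration; iter cap per the undistortion contract
undistort_normalized <- function(xd, yd, K, max_iter = 20L, tol = 1e-12) {
  if (K$k1 == 0 && K$k2 == 0) return(list(x = xd, y = yd))
  xn <- xd; yn <- yd
  for (i in seq_len(max_iter)) {
    r2 <- xn^2 + yn^2
    s <- 1 + K$k1 * r2 + K$k2 * r2^2
    x_new <- xd / s
    y_new <- yd / s
    delta <- max(abs(x_new - xn), abs(y_new - yn))
    xn <- x_new; yn <- y_new
    if (delta < tol) return(list(x = xn, y = yn))
  }
  fs_stop("undistortion did not converge within iteration cap",
          "fishstereo_undistort_nonconvergent")
}

#' Project a camera-frame point to pixel coordinates
#'
#' Perspective division by depth, radial distortion (when `k1`/`k2` are
#' nonzero), then the affine pixel mapping through the intrinsic matrix.
#'
#' @param p length-3 point in the camera frame (mm); must have `z > 0`.
#' @param K a [camera_intrinsics()] object.
#' @return length-2 pixel coordinates `(u, v)`.
#' @export
camera_to_pixel <- function(p, K) {
  stopifnot(inherits(K, "camera_intrinsics"))
  fs_assert(length(p) == 3L && all(is.finite(p)), "point must be a finite 3-vector")
  if (p[3] <= 0)
    fs_stop("point at or behind camera (z <= 0)", "fishstereo_behind_camera")
  xn <- p[1] / p[3]
  yn <- p[2] / p[3]
  d <- distort_normalized(xn, yn, K)
  normalized_to_pixel(d$x, d$y, K)
}

# (xn, yn) normalized -> (u, v) px through A
normalized_to_pixel <- function(xn, yn, K) {
  alpha <- K$f_mm / K$dx_mm
  beta <- K$f_mm / K$dy_mm
  c(alpha * xn + K$skew * yn + K$u0, beta * yn + K$v0)
}

# (u, v) px -> distorted normalized coordinates (A^{-1} applied)
pixel_to_normalized <- function(pix, K) {
  alpha <- K$f_mm / K$dx_mm
  beta <- K$f_mm / K$dy_mm
  yn <- (pix[2] - K$v0) / beta
  xn <- (pix[1] - K$u0 - K$skew * yn) / alpha
  c(xn, yn)
}

#' Lift a pixel to metric image-plane coordinates
#'
#' Inverts the pixel mapping and the radial distortion (fixed-point, at most
#' 20 iterations) and returns coordinates on the image plane at distance `f`,
#' in mm. This is the exact inverse of [camera_to_pixel()] up to perspective
#' scale: the returned point is \eqn{(f x_c/z_c, f y_c/z_c)}.
#'
#' @param pix length-2 pixel coordinates `(u, v)`.
#' @param K a [camera_intrinsics()] object.
#' @return length-2 metric image coordinates in mm.
#' @export
pixel_to_metric <- function(pix, K) {
  stopifnot(inherits(K, "camera_intrinsics"))
  n <- pixel_to_normalized(pix, K)
  u <- undistort_normalized(n[1], n[2], K)
  c(K$f_mm * u$x, K$f_mm * u$y)
}

# inverse of pixel_to_metric: metric mm on the focal plane -> pixels,
# re-applying distortion so the pair round-trips exactly
metric_to_pixel <- function(m, K) {
  d <- distort_normalized(m[1] / K$f_mm, m[2] / K$f_mm, K)
  normalized_to_pixel(d$x, d$y, K)
}

#' Projection matrix M = A [R | t]
#'
#' The 3x4 matrix mapping homogeneous world coordinates to homogeneous pixel
#' coordinates for a distortion-free camera.
#'
#' @param K a [camera_intrinsics()] object.
#' @param ext a [camera_extrinsics()] object.
#' @return 3x4 numeric matrix of class `projection_matrix`.
#' @export
projection_matrix <- function(K, ext) {
  stopifnot(inherits(K, "camera_intrinsics"), inherits(ext, "camera_extrinsics"))
  M <- intrinsic_matrix(K) %*% cbind(ext$R, ext$t)
  class(M) <- c("projection_matrix", class(M))
  M
}

# project a world point through a 3x4 matrix; returns (u, v)
project_point <- function(M, p) {
  h <- as.numeric(M %*% c(p, 1))
  if (h[3] <= 0)
    fs_stop("point at or behind camera (z <= 0)", "fishstereo_behind_camera")
  h[1:2] / h[3]
}
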