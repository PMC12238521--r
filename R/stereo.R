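#' Calibrated stereo rig with flat ports
#'
#' Bundles per-camera intrinsics, extrinsics and flat-port geometry for a
#' binocular system sharing one world frame (by convention the left-camera
#' frame). The baseline must be positive and both projection matrices full
#' rank.
#'
#' @param left,right lists with elements `K` ([camera_intrinsics()]), `ext`
#'   ([camera_extrinsics()]) and `port` ([flat_port()]).
#' @param image_size image dimensions `(width, height)` in px, used for
#'   visibility decisions.
#' @return An object of class `stereo_rig`.
#' @export
stereo_rig <- function(left, right, image_size = c(640, 480)) {
  for (cam in list(left, right)) {
    stopifnot(inherits(cam$K, "camera_intrinsics"),
              inherits(cam$ext, "camera_extrinsics"),
              inherits(cam$port, "flat_port"))
  }
  c_left <- -crossprod(left$ext$R, left$ext$t)
  c_right <- -crossprod(right$ext$R, right$ext$t)
  baseline <- sqrt(sum((c_left - c_right)^2))
  fs_assert(baseline > 0, "camera centers coincide (zero baseline)",
            "fishstereo_degenerate_geometry")
  structure(list(left = left, right = right,
                 image_size = as.numeric(image_size), baseline = baseline),
            class = "stereo_rig")
}

#' @export
print.stereo_rig <- function(x, ...) {
  cat(sprintf("stereo_rig: baseline %.2f mm, image %d x %d px\n",
              x$baseline, x$image_size[1], x$image_size[2]))
  invisible(x)
}

#' Least-squares triangulation of a stereo correspondence
#'
#' Builds the 4 x 3 linear system obtained by eliminating the projective
#' depths from the two pinhole projections,
#' \deqn{(u\, m_{3\cdot} - m_{1\cdot}) \cdot (X, Y, Z)^T = m_{14} - u\, m_{34}}
#' (one such pair per camera), and returns its least-squares solution via QR
#' factorization. The world point is expressed in the frame the projection
#' matrices share.
#'
#' @param p_left,p_right pixel coordinates `(u, v)` in the two views
#'   (distortion-free, i.e. consistent with the linear projection matrices).
#' @param M1,M2 3x4 projection matrices (see [projection_matrix()]).
#' @return length-3 world point, mm.
#' @export
triangulate <- function(p_left, p_right, M1, M2) {
  check_ray_geometry(p_left, p_right, M1, M2)
  A <- rbind(
    p_left[1] * M1[3, 1:3] - M1[1, 1:3],
    p_left[2] * M1[3, 1:3] - M1[2, 1:3],
    p_right[1] * M2[3, 1:3] - M2[1, 1:3],
    p_right[2] * M2[3, 1:3] - M2[2, 1:3])
  b <- c(M1[1, 4] - p_left[1] * M1[3, 4],
         M1[2, 4] - p_left[2] * M1[3, 4],
         M2[1, 4] - p_right[1] * M2[3, 4],
         M2[2, 4] - p_right[2] * M2[3, 4])
  as.numeric(qr.coef(qr(A), b))
}

# back-projected ray of a pixel through a 3x4 projection matrix
back_project_ray <- function(pix, M) {
  Minv <- solve(M[, 1:3])
  center <- as.numeric(-Minv %*% M[, 4])
  dir <- as.numeric(Minv %*% c(pix, 1))
  dir <- dir / sqrt(sum(dir^2))
  list(center = center, dir = dir)
}

check_ray_geometry <- function(p_left, p_right, M1, M2, min_angle = 1e-8) {
  r1 <- back_project_ray(p_left, M1)
  r2 <- back_project_ray(p_right, M2)
  ca <- abs(sum(r1$dir * r2$dir))
  angle <- acos(min(1, ca))
  if (angle <= min_angle)
    fs_stop("(near-)parallel viewing rays: triangulation is degenerate",
            "fishstereo_degenerate_geometry")
  invisible(TRUE)
}

#' Euclidean fish body length
#'
#' \deqn{L = \sqrt{(X_H - X_T)^2 + (Y_H - Y_T)^2 + (Z_H - Z_T)^2}}
#' between the 3D head (snout) and tail points.
#'
#' @param head,tail length-3 world points, mm.
#' @return Length in mm.
#' @export
fish_length <- function(head, tail) {
  fs_assert(length(head) == 3L && length(tail) == 3L,
            "head and tail must be 3D points")
  sqrt(sum((head - tail)^2))
}

#' Relative error of a length measurement
#'
#' \deqn{RE = |L_t - L_a| / L_a \times 100\%} with \eqn{L_t} the estimated
#' and \eqn{L_a} the reference (manually measured) length.
#'
#' @param L_t estimated length, mm.
#' @param L_a reference length, mm (> 0).
#' @return Relative error in percent.
#' @export
relative_error <- function(L_t, L_a) {
  if (any(L_a <= 0))
    fs_stop("reference length must be > 0", "fishstereo_zero_reference")
  abs(L_t - L_a) / L_a * 100
}

#' Mean relative percentage error
#'
#' Arithmetic mean of [relative_error()] over estimated/reference length
#' pairs.
#'
#' @param pairs two-column matrix or data.frame, columns `(L_t, L_a)`.
#' @return MRPE in percent.
#' @export
mrpe <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0)
    fs_stop("need at least one length pair", "fishstereo_empty")
  mean(relative_error(pairs[, 1], pairs[, 2]))
}

required_keypoints <- function(tail_rule) {
  tail <- switch(tail_rule,
    midpoint = c("tail_fin1", "tail_fin2"),
    tail_fin1 = "tail_fin1",
    tail_fin2 = "tail_fin2",
    fs_stop("tail_rule must be one of midpoint, tail_fin1, tail_fin2",
            "fishstereo_invalid"))
  c("mouth", tail)
}

# corrected pixel -> ideal (distortion-free) pixel consistent with A [R|t]
ideal_pixel <- function(pix, K) {
  m <- pixel_to_metric(pix, K)
  normalized_to_pixel(m[1] / K$f_mm, m[2] / K$f_mm, K)
}

#' Measure one fish from a stereo keypoint pair
#'
#' End-to-end single-fish measurement: refraction-correct the keypoints of
#' both views (unless `model = "none"`), triangulate every keypoint visible
#' in both views, and compute the body length between the 3D mouth point and
#' the tail point. The tail point is, by default, the midpoint of the two
#' tail-fin landmarks (`tail_rule = "midpoint"`); either fin can be selected
#' instead.
#'
#' @param kps_left,kps_right [fish_keypoints()] in the left/right view.
#' @param rig a [stereo_rig()].
#' @param model refraction model (`"single"`, `"parallel"`, `"tilted"`) or
#'   `"none"` to skip correction.
#' @param tail_rule `"midpoint"` (default), `"tail_fin1"` or `"tail_fin2"`.
#' @return list of class `fish_measurement`: `points3d` (9 x 3, NA where a
#'   keypoint was not triangulated), `length_mm`, `head_point`,
#'   `tail_point`, `residuals_px` (per-keypoint RMS reprojection error).
#' @export
measure_fish <- function(kps_left, kps_right, rig, model = "parallel",
                         tail_rule = "midpoint") {
  stopifnot(inherits(rig, "stereo_rig"))
  req <- required_keypoints(tail_rule)
  if (model != "none") {
    kps_left <- correct_keypoints(kps_left, rig$left$K, rig$left$port, model)
    kps_right <- correct_keypoints(kps_right, rig$right$K, rig$right$port, model)
  }
  vis <- kps_left$points[, "visibility"] == 1 &
    kps_right$points[, "visibility"] == 1
  missing <- setdiff(req, FISH_KEYPOINT_NAMES[vis])
  if (length(missing) > 0)
    fs_stop(sprintf("required keypoint(s) not visible in both views: %s",
                    paste(missing, collapse = ", ")),
            "fishstereo_missing_keypoint")
  M1 <- projection_matrix(rig$left$K, rig$left$ext)
  M2 <- projection_matrix(rig$right$K, rig$right$ext)
  pts3d <- matrix(NA_real_, 9, 3,
                  dimnames = list(FISH_KEYPOINT_NAMES, c("X", "Y", "Z")))
  resid <- rep(NA_real_, 9)
  names(resid) <- FISH_KEYPOINT_NAMES
  for (i in which(vis)) {
    pl <- ideal_pixel(kps_left$points[i, c("u", "v")], rig$left$K)
    pr <- ideal_pixel(kps_right$points[i, c("u", "v")], rig$right$K)
    P <- tryCatch(triangulate(pl, pr, M1, M2),
                  fishstereo_degenerate_geometry = function(e) {
                    fs_stop(sprintf("keypoint '%s': %s",
                                    FISH_KEYPOINT_NAMES[i], conditionMessage(e)),
                            "fishstereo_degenerate_geometry")
                  })
    pts3d[i, ] <- P
    e1 <- project_point(M1, P) - pl
    e2 <- project_point(M2, P) - pr
    resid[i] <- sqrt(mean(c(sum(e1^2), sum(e2^2))))
  }
  head_point <- pts3d["mouth", ]
  tail_point <- switch(tail_rule,
    midpoint = (pts3d["tail_fin1", ] + pts3d["tail_fin2", ]) / 2,
    tail_fin1 = pts3d["tail_fin1", ],
    tail_fin2 = pts3d["tail_fin2", ])
  structure(list(points3d = pts3d,
                 length_mm = fish_length(head_point, tail_point),
                 head_point = head_point, tail_point = tail_point,
                 residuals_px = resid),
            class = "fish_measurement")
}

#' @export
print.fish_measurement <- function(x, ...) {
  cat(sprintf("fish_measurement: length %.3f mm (%d keypoints triangulated)\n",
              x$length_mm, sum(!is.na(x$points3d[, 1]))))
  invisible(x)
}
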