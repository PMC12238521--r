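#' Planar target correspondences for one view
#'
#' Pairs of checkerboard corner positions on the target plane (Z = 0, mm)
#' and their detected pixel locations in one image.
#'
#' @param world_xy n x 2 matrix of `(X, Y)` mm on the target plane.
#' @param pixels n x 2 matrix of `(u, v)` px.
#' @param view_id identifier of the view.
#' @return An object of class `planar_correspondences`.
#' @export
planar_correspondences <- function(world_xy, pixels, view_id = 1L) {
  world_xy <- as.matrix(world_xy)
  pixels <- as.matrix(pixels)
  fs_assert(ncol(world_xy) == 2L && ncol(pixels) == 2L &&
              nrow(world_xy) == nrow(pixels),
            "world and pixel point lists must be n x 2 with equal n")
  fs_assert(nrow(world_xy) >= 4L,
            "at least 4 correspondences are required",
            "fishstereo_degenerate_configuration")
  structure(list(world_xy = world_xy, pixels = pixels, view_id = view_id),
            class = "planar_correspondences")
}

# similarity normalization for DLT conditioning (centroid to origin,
# mean distance sqrt(2))
normalize_points <- function(P) {
  centroid <- colMeans(P)
  d <- sqrt(rowSums(sweep(P, 2, centroid)^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  Tm <- matrix(c(s, 0, -s * centroid[1],
                 0, s, -s * centroid[2],
                 0, 0, 1), 3, 3, byrow = TRUE)
  Ph <- cbind(P, 1) %*% t(Tm)
  list(points = Ph[, 1:2, drop = FALSE], T = Tm)
}

points_collinear <- function(P, tol = 1e-8) {
  Pc <- sweep(P, 2, colMeans(P))
  sv <- svd(Pc)$d
  sv[2] < tol * max(sv[1], 1)
}

#' Estimate a plane-to-image homography (DLT)
#'
#' Direct linear transform with Hartley point normalization, solving the
#' algebraic least-squares problem for the 3x3 homography mapping target
#' plane coordinates to pixels, \eqn{s (u, v, 1)^T = H (X, Y, 1)^T}.
#' The result is Frobenius-normalized with `h33 >= 0`.
#'
#' @param c a [planar_correspondences()] object (>= 4 points,
#'   non-collinear).
#' @return 3x3 matrix of class `homography`.
#' @export
estimate_homography <- function(c) {
  stopifnot(inherits(c, "planar_correspondences"))
  if (points_collinear(c$world_xy))
    fs_stop("degenerate configuration: target points are collinear",
            "fishstereo_degenerate_configuration")
  nw <- normalize_points(c$world_xy)
  np <- normalize_points(c$pixels)
  n <- nrow(c$world_xy)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- nw$points[i, 1]; Y <- nw$points[i, 2]
    u <- np$points[i, 1]; v <- np$points[i, 2]
    A[2 * i - 1, ] <- c(-X, -Y, -1, 0, 0, 0, u * X, u * Y, u)
    A[2 * i, ] <- c(0, 0, 0, -X, -Y, -1, v * X, v * Y, v)
  }
  h <- svd(A, nu = 0)$v[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(np$T) %*% Hn %*% nw$T
  H <- H / sqrt(sum(H^2))
  if (H[3, 3] < 0) H <- -H
  class(H) <- c("homography", class(H))
  H
}

# map plane points (n x 2) through a homography, returning pixels
apply_homography <- function(H, P) {
  Ph <- cbind(P, 1) %*% t(unclass(H))
  Ph[, 1:2, drop = FALSE] / Ph[, 3]
}

# v_ij vector of the absolute-conic constraints for columns i, j of H
conic_row <- function(H, i, j) {
  h_i <- H[, i]; h_j <- H[, j]
  c(h_i[1] * h_j[1],
    h_i[1] * h_j[2] + h_i[2] * h_j[1],
    h_i[2] * h_j[2],
    h_i[3] * h_j[1] + h_i[1] * h_j[3],
    h_i[3] * h_j[2] + h_i[2] * h_j[3],
    h_i[3] * h_j[3])
}

#' Intrinsics from planar-target homographies (Zhang's method)
#'
#' Each view's homography contributes the two linear constraints on the
#' image of the absolute conic \eqn{B = A^{-T} A^{-1}} that follow from the
#' orthonormality of the rotation columns:
#' \eqn{h_1^T B h_2 = 0} and \eqn{h_1^T B h_1 = h_2^T B h_2}. With at least
#' three views in distinct poses the stacked system determines `B` up to
#' scale; the intrinsic matrix is recovered from `B` in closed form
#' (5 unknowns: alpha, beta, gamma, u0, v0).
#'
#' Planar calibration determines only the pixel-unit quantities
#' \eqn{\alpha = f/dx} and \eqn{\beta = f/dy}; the physical focal length is
#' a gauge choice supplied by `f_mm` (it cancels in all projections).
#'
#' @param hs list of [estimate_homography()] results from distinct poses
#'   (>= 3).
#' @param f_mm nominal focal length used to populate the returned
#'   [camera_intrinsics()] (default 1).
#' @return A [camera_intrinsics()] object.
#' @export
intrinsics_from_homographies <- function(hs, f_mm = 1) {
  if (length(hs) < 3L)
    fs_stop("at least 3 views in distinct poses are required",
            "fishstereo_insufficient_views")
  V <- do.call(rbind, lapply(hs, function(H) {
    rbind(conic_row(H, 1, 2),
          conic_row(H, 1, 1) - conic_row(H, 2, 2))
  }))
  sv <- svd(V, nu = 0)
  # distinct poses leave a 1-D nullspace; repeated poses collapse the rank
  if (sv$d[5] < 1e-9 * sv$d[1])
    fs_stop("degenerate view set: target poses are not distinct",
            "fishstereo_degenerate_configuration")
  b <- sv$v[, 6]
  if (b[1] < 0) b <- -b
  B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
  den <- B11 * B22 - B12^2
  if (B11 <= 0 || den <= 0)
    fs_stop("recovered conic is not positive definite (degenerate poses)",
            "fishstereo_degenerate_configuration")
  v0 <- (B12 * B13 - B11 * B23) / den
  lambda <- B33 - (B13^2 + v0 * (B12 * B13 - B11 * B23)) / B11
  if (lambda / B11 <= 0 || lambda * B11 / den <= 0)
    fs_stop("recovered conic is not positive definite (degenerate poses)",
            "fishstereo_degenerate_configuration")
  alpha <- sqrt(lambda / B11)
  beta <- sqrt(lambda * B11 / den)
  gamma <- -B12 * alpha^2 * beta / lambda
  u0 <- gamma * v0 / beta - B13 * alpha^2 / lambda
  camera_intrinsics(f_mm = f_mm, dx_mm = f_mm / alpha, dy_mm = f_mm / beta,
                    skew = gamma, u0 = u0, v0 = v0)
}

#' Target pose from a homography and known intrinsics
#'
#' Decomposes \eqn{H = \lambda A [r_1\, r_2\, t]}:
#' \eqn{r_1 = \lambda^{-1} A^{-1} h_1}, \eqn{r_2 = \lambda^{-1} A^{-1} h_2}
#' with \eqn{\lambda = 1/\lVert A^{-1} h_1 \rVert}; \eqn{r_3 = r_1 \times
#' r_2}; \eqn{t = \lambda A^{-1} h_3}. The rotation is re-orthonormalized by the
#' nearest-rotation (SVD) projection, and the homography sign is fixed so
#' the target sits in front of the camera (`t_z > 0`).
#'
#' @param h a [estimate_homography()] result.
#' @param K a [camera_intrinsics()] object.
#' @return A [camera_extrinsics()] object.
#' @export
extrinsics_from_homography <- function(h, K) {
  A <- intrinsic_matrix(K)
  H <- unclass(h)
  Ainv_h3 <- solve(A, H[, 3])
  lambda <- 1 / sqrt(sum(solve(A, H[, 1])^2))
  if (lambda * Ainv_h3[3] < 0) {
    H <- -H
    Ainv_h3 <- -Ainv_h3
  }
  r1 <- lambda * solve(A, H[, 1])
  r2 <- lambda * solve(A, H[, 2])
  r3 <- cross3(r1, r2)
  R <- nearest_rotation(cbind(r1, r2, r3))
  t <- lambda * Ainv_h3
  camera_extrinsics(R = R, t = t)
}

#' Calibration reprojection-error report
#'
#' Reprojects the target corners through the calibrated camera and reports
#' the per-point pixel residual, per-view mean, and global RMS.
#'
#' @param views list of [planar_correspondences()].
#' @param K calibrated [camera_intrinsics()].
#' @param exts list of [camera_extrinsics()], one per view.
#' @return list with `points` (data.frame view_id, X_mm, Y_mm, u_px, v_px,
#'   u_hat, v_hat, residual_px), `per_view` (data.frame view_id, mean
#'   residual), `rms` (global RMS residual in px).
#' @export
reprojection_report <- function(views, K, exts) {
  fs_assert(length(views) == length(exts),
            "need one extrinsics per view")
  A <- intrinsic_matrix(K)
  rows <- lapply(seq_along(views), function(i) {
    v <- views[[i]]
    P <- A %*% cbind(exts[[i]]$R[, 1:2], exts[[i]]$t)
    proj <- apply_homography(P, v$world_xy)
    res <- sqrt(rowSums((proj - v$pixels)^2))
    data.frame(view_id = v$view_id,
               X_mm = v$world_xy[, 1], Y_mm = v$world_xy[, 2],
               u_px = v$pixels[, 1], v_px = v$pixels[, 2],
               u_hat = proj[, 1], v_hat = proj[, 2],
               residual_px = res)
  })
  points <- do.call(rbind, rows)
  per_view <- stats::aggregate(residual_px ~ view_id, points, mean)
  names(per_view)[2] <- "mean_residual_px"
  list(points = points, per_view = per_view,
       rms = sqrt(mean(points$residual_px^2)))
}

# axis-angle <-> rotation matrix (Rodrigues), for the refinement parameterization
rotation_to_rvec <- function(R) {
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
  if (ang < 1e-12) return(c(0, 0, 0))
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(ang))
  axis * ang
}

rvec_to_rotation <- function(rvec) {
  ang <- sqrt(sum(rvec^2))
  if (ang < 1e-12) return(diag(3))
  ax <- rvec / ang
  Kx <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + sin(ang) * Kx + (1 - cos(ang)) * Kx %*% Kx
}

# joint Gauss-Newton refinement of (alpha, beta, gamma, u0, v0) and every
# view pose, minimizing the total squared reprojection error -- the
# maximum-likelihood polish that conventionally follows the closed-form
# solution
refine_calibration <- function(views, K, exts, max_iter = 25L) {
  theta <- c(K$f_mm / K$dx_mm, K$f_mm / K$dy_mm, K$skew, K$u0, K$v0,
             unlist(lapply(exts, function(e) c(rotation_to_rvec(e$R), e$t))))
  residuals <- function(theta) {
    A <- matrix(c(theta[1], theta[3], theta[4],
                  0, theta[2], theta[5],
                  0, 0, 1), 3, 3, byrow = TRUE)
    unlist(lapply(seq_along(views), function(i) {
      off <- 5 + (i - 1) * 6
      R <- rvec_to_rotation(theta[off + 1:3])
      P <- A %*% cbind(R[, 1:2], theta[off + 4:6])
      proj <- apply_homography(P, views[[i]]$world_xy)
      as.numeric(proj - views[[i]]$pixels)
    }))
  }
  for (it in seq_len(max_iter)) {
    r0 <- residuals(theta)
    J <- vapply(seq_along(theta), function(j) {
      h <- max(1e-6, abs(theta[j]) * 1e-7)
      tp <- theta
      tp[j] <- tp[j] + h
      (residuals(tp) - r0) / h
    }, numeric(length(r0)))
    step <- qr.coef(qr(J), -r0)
    theta <- theta + step
    if (max(abs(step) / pmax(abs(theta), 1)) < 1e-12) break
  }
  K_out <- camera_intrinsics(f_mm = K$f_mm, dx_mm = K$f_mm / theta[1],
                             dy_mm = K$f_mm / theta[2], skew = theta[3],
                             u0 = theta[4], v0 = theta[5])
  exts_out <- lapply(seq_along(views), function(i) {
    off <- 5 + (i - 1) * 6
    camera_extrinsics(R = rvec_to_rotation(theta[off + 1:3]),
                      t = theta[off + 4:6])
  })
  list(K = K_out, extrinsics = exts_out)
}

#' Calibrate a camera from planar views
#'
#' Runs [estimate_homography()] on every view,
#' [intrinsics_from_homographies()], and [extrinsics_from_homography()] per
#' view, then (by default) polishes all parameters jointly by minimizing
#' the total squared reprojection error -- the maximum-likelihood step that
#' conventionally concludes planar calibration and is what makes the
#' reported residuals track the corner noise level. Returns the parameters
#' together with a [reprojection_report()].
#'
#' @param views list of [planar_correspondences()] (>= 3 distinct poses).
#' @param f_mm nominal focal length gauge (see
#'   [intrinsics_from_homographies()]).
#' @param refine logical; polish the closed-form solution by nonlinear
#'   least squares (default TRUE). `FALSE` returns the purely linear
#'   estimate.
#' @return list with `K`, `extrinsics` (list), `report`.
#' @export
calibrate_camera <- function(views, f_mm = 1, refine = TRUE) {
  hs <- lapply(views, estimate_homography)
  K <- intrinsics_from_homographies(hs, f_mm = f_mm)
  exts <- lapply(hs, extrinsics_from_homography, K = K)
  if (refine) {
    pol <- refine_calibration(views, K, exts)
    K <- pol$K
    exts <- pol$extrinsics
  }
  list(K = K, extrinsics = exts,
       report = reprojection_report(views, K, exts))
}

#' Read planar corner correspondences from CSV
#'
#' Expects columns `view_id`, `X_mm`, `Y_mm`, `u_px`, `v_px`.
#'
#' @param path CSV path.
#' @return list of [planar_correspondences()], one per view.
#' @export
read_correspondences <- function(path) {
  fs_assert(file.exists(path), sprintf("file not found: %s", path),
            "fishstereo_io")
  df <- utils::read.csv(path)
  need <- c("view_id", "X_mm", "Y_mm", "u_px", "v_px")
  fs_assert(all(need %in% names(df)),
            sprintf("correspondence CSV must have columns: %s",
                    paste(need, collapse = ", ")), "fishstereo_schema")
  lapply(split(df, df$view_id), function(v) {
    planar_correspondences(as.matrix(v[, c("X_mm", "Y_mm")]),
                           as.matrix(v[, c("u_px", "v_px")]),
                           view_id = v$view_id[1])
  })
}
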