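# Independent oracles and fixture builders shared across the test files.

# Closed-form two-ray midpoint triangulation: back-project both pixels,
# find the closest points on the two rays, return their midpoint. Solved
# via the 2x2 normal equations of the inter-ray distance -- an independent
# route from the 4x3 least-squares system under test.
midpoint_triangulate <- function(p_left, p_right, M1, M2) {
  ray <- function(pix, M) {
    Minv <- solve(M[, 1:3])
    list(c = as.numeric(-Minv %*% M[, 4]),
         d = as.numeric(Minv %*% c(pix, 1)))
  }
  r1 <- ray(p_left, M1)
  r2 <- ray(p_right, M2)
  d1 <- r1$d / sqrt(sum(r1$d^2))
  d2 <- r2$d / sqrt(sum(r2$d^2))
  w <- r1$c - r2$c
  a <- sum(d1 * d1); b <- sum(d1 * d2); cc <- sum(d2 * d2)
  dd <- sum(d1 * w); e <- sum(d2 * w)
  den <- a * cc - b * b
  s <- (b * e - cc * dd) / den
  t <- (a * e - b * dd) / den
  (r1$c + s * d1 + r2$c + t * d2) / 2
}

# a randomized but valid stereo rig: verged cameras with a positive baseline
random_rig <- function() {
  K1 <- camera_intrinsics(f_mm = runif(1, 3, 6), dx_mm = 0.003, dy_mm = 0.003,
                          u0 = runif(1, 300, 340), v0 = runif(1, 220, 260))
  K2 <- camera_intrinsics(f_mm = runif(1, 3, 6), dx_mm = 0.003, dy_mm = 0.003,
                          u0 = runif(1, 300, 340), v0 = runif(1, 220, 260))
  baseline <- runif(1, 40, 120)
  verge <- runif(1, -0.05, 0.05)
  R2 <- matrix(c(cos(verge), 0, sin(verge),
                 0, 1, 0,
                 -sin(verge), 0, cos(verge)), 3, 3, byrow = TRUE)
  ext1 <- camera_extrinsics()
  ext2 <- camera_extrinsics(R = R2, t = as.numeric(-R2 %*% c(baseline, 0, 0)))
  port <- flat_port(d_mm = K1$f_mm, T_mm = 2.8)
  stereo_rig(left = list(K = K1, ext = ext1, port = port),
             right = list(K = K2, ext = ext2, port = port))
}

# project a world point into both cameras of a rig (no distortion path)
project_pair <- function(P, rig) {
  list(left = camera_to_pixel(world_to_camera(P, rig$left$ext), rig$left$K),
       right = camera_to_pixel(world_to_camera(P, rig$right$ext), rig$right$K))
}

# a hand-built fish_keypoints object with all points visible
make_kps <- function(u = seq(100, 500, length.out = 9),
                     v = seq(120, 360, length.out = 9),
                     visibility = rep(1, 9), bbox = c(90, 110, 420, 260)) {
  fish_keypoints(cbind(u, v, visibility), bbox = bbox)
}

fig11_port <- function(tilt_rad = 0)
  flat_port(d_mm = 3, T_mm = 2.8, n_air = 1, n_glass = 1.6, n_water = 1.33,
            tilt_rad = tilt_rad)
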