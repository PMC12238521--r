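test_that("homography estimation recovers exact mappings", {
  # identity: unit square to itself
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1, 0.3, 0.6), ncol = 2, byrow = TRUE)
  H <- estimate_homography(planar_correspondences(sq, sq))
  expect_equal(unclass(H) / H[3, 3], diag(3), tolerance = 1e-9)

  # random known homography from 20 points
  set.seed(42)
  for (rep in 1:5) {
    Ht <- matrix(rnorm(9), 3, 3) + 3 * diag(3)
    W <- cbind(runif(20, -50, 50), runif(20, -50, 50))
    Ph <- cbind(W, 1) %*% t(Ht)
    px <- Ph[, 1:2] / Ph[, 3]
    Hhat <- estimate_homography(planar_correspondences(W, px))
    Ht_n <- Ht / sqrt(sum(Ht^2)) * sign(Ht[3, 3])
    expect_equal(unclass(Hhat), Ht_n, tolerance = 1e-8)
  }
})

test_that("degenerate correspondence sets are rejected", {
  W3 <- matrix(c(0, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
  expect_error(planar_correspondences(W3, W3),
               class = "fishstereo_degenerate_configuration")
  Wcol <- cbind(1:6, 2 * (1:6) + 1)  # collinear world points
  expect_error(estimate_homography(planar_correspondences(Wcol, Wcol)),
               class = "fishstereo_degenerate_configuration")
})

test_that("intrinsics and extrinsics are recovered from noiseless views", {
  K_true <- camera_intrinsics(f_mm = 3, dx_mm = 0.003, dy_mm = 0.0031,
                              u0 = 321.5, v0 = 238.2)
  views <- make_checkerboard_views(K_true, n_views = 4, seed = 3)
  cal <- calibrate_camera(views, f_mm = 3)
  A_hat <- intrinsic_matrix(cal$K)
  A_true <- intrinsic_matrix(K_true)
  expect_equal(A_hat, A_true, tolerance = 1e-6)
  expect_lt(cal$report$rms, 1e-6)
  for (ext in cal$extrinsics) {
    expect_equal(crossprod(ext$R), diag(3), tolerance = 1e-9)
    expect_gt(ext$t[3], 0)  # target in front of the camera
  }
  # estimate is invariant to view order
  cal_rev <- calibrate_camera(rev(views), f_mm = 3)
  expect_equal(intrinsic_matrix(cal_rev$K), A_hat, tolerance = 1e-9)
})

test_that("extrinsics round-trip through a constructed homography", {
  K <- camera_intrinsics(f_mm = 3, dx_mm = 0.003, dy_mm = 0.003,
                         u0 = 320, v0 = 240)
  A <- intrinsic_matrix(K)
  R <- fishstereo:::euler_rotation(0.2, -0.3, 0.1)
  t <- c(12, -8, 500)
  H <- A %*% cbind(R[, 1:2], t)
  H <- H / sqrt(sum(H^2))
  class(H) <- c("homography", class(H))
  ext <- extrinsics_from_homography(H, K)
  expect_equal(ext$R, R, tolerance = 1e-6)
  expect_equal(ext$t, t, tolerance = 1e-6)

  # frontal target at distance Z gives t ~ (0, 0, Z)
  Hf <- A %*% cbind(diag(3)[, 1:2], c(0, 0, 600))
  class(Hf) <- c("homography", class(Hf))
  extf <- extrinsics_from_homography(Hf, K)
  expect_equal(extf$t, c(0, 0, 600), tolerance = 1e-6)
})

test_that("too few or coincident views are rejected", {
  K_true <- camera_intrinsics(f_mm = 3, dx_mm = 0.003, dy_mm = 0.003,
                              u0 = 320, v0 = 240)
  views <- make_checkerboard_views(K_true, n_views = 3, seed = 5)
  hs <- lapply(views, estimate_homography)
  expect_error(intrinsics_from_homographies(hs[1:2]),
               class = "fishstereo_insufficient_views")
  expect_error(intrinsics_from_homographies(list(hs[[1]], hs[[1]], hs[[1]])),
               class = "fishstereo_degenerate_configuration")
})

test_that("reprojection RMS tracks the injected corner noise", {
  K_true <- camera_intrinsics(f_mm = 3, dx_mm = 0.003, dy_mm = 0.003,
                              u0 = 320, v0 = 240)
  rms <- vapply(1:10, function(s) {
    views <- make_checkerboard_views(K_true, n_views = 5,
                                     noise_sigma_px = 0.5, seed = s)
    cal <- calibrate_camera(views, f_mm = 3)
    cal$report$rms
  }, numeric(1))
  expect_gt(mean(rms), 0.3)
  expect_lt(mean(rms), 0.7)

  # residual tables are invariant to relabeling of views
  views <- make_checkerboard_views(K_true, n_views = 4, seed = 1)
  cal <- calibrate_camera(views, f_mm = 3)
  rep2 <- reprojection_report(rev(views), cal$K, rev(cal$extrinsics))
  expect_equal(rep2$rms, cal$report$rms, tolerance = 1e-12)
})

test_that("correspondence CSV round trip", {
  K_true <- camera_intrinsics(f_mm = 3, dx_mm = 0.003, dy_mm = 0.003,
                              u0 = 320, v0 = 240)
  views <- make_checkerboard_views(K_true, n_views = 3, seed = 2)
  df <- do.call(rbind, lapply(views, function(v) {
    data.frame(view_id = v$view_id, X_mm = v$world_xy[, 1],
               Y_mm = v$world_xy[, 2], u_px = v$pixels[, 1],
               v_px = v$pixels[, 2])
  }))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  views2 <- read_correspondences(path)
  expect_length(views2, 3)
  cal <- calibrate_camera(views2, f_mm = 3)
  expect_equal(intrinsic_matrix(cal$K), intrinsic_matrix(K_true),
               tolerance = 1e-6)
})
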