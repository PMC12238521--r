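test_that("snell_refract evaluates Snell's law and flags TIR", {
  expect_equal(snell_refract(0, 1.33, 1.0), 0)
  # 30 degrees, water to air: arcsin(1.33 * sin 30 / 1) = arcsin(0.665)
  expect_equal(snell_refract(pi / 6, 1.33, 1.0), asin(0.665),
               tolerance = 1e-12)
  # 60 degrees water to air exceeds the critical angle (1.33 sin60 > 1)
  expect_error(snell_refract(pi / 3, 1.33, 1.0), class = "fishstereo_tir")
  # into a denser medium refraction always exists
  expect_equal(snell_refract(pi / 3, 1.0, 1.6), asin(sin(pi / 3) / 1.6))
})

test_that("single-refraction map matches its closed form and limits", {
  port <- fig11_port()
  expect_identical(correct_single(0, port), 0)
  # hand evaluation: d tan(arcsin(sin(arctan(1)) / 1.33)) at d = 3
  expect_equal(correct_single(3, port),
               3 * tan(asin(sin(atan(1)) / 1.33)), tolerance = 1e-12)
  expect_equal(correct_single(3, port), 1.8832, tolerance = 1e-4)
  # small-coordinate limit: x_a -> x_r / 1.33
  expect_equal(correct_single(1e-6, port), 1e-6 / 1.33, tolerance = 1e-12)
  # odd symmetry
  x <- seq(0.1, 2.5, length.out = 7)
  expect_equal(correct_single(-x, port), -correct_single(x, port))
  expect_equal(observe_single(correct_single(x, port), port), x,
               tolerance = 1e-12)
})

test_that("parallel-system maps evaluate the slab formulas", {
  port <- fig11_port()
  a <- 20 * pi / 180
  # direct evaluation of the slab formulas at alpha = 20 degrees
  x_a <- 2.8 * tan(asin(sin(a) / 1.6)) + 0.2 * tan(a)
  x_r <- 2.8 * tan(asin(1.33 * sin(a) / 1.6)) + 0.2 * tan(asin(1.33 * sin(a)))
  expect_equal(x_a, 0.6855, tolerance = 1e-4)
  expect_equal(x_r, 0.9325, tolerance = 1e-4)
  expect_equal(observe_parallel(x_a, port), x_r, tolerance = 1e-9)
  expect_equal(correct_parallel(x_r, port), x_a, tolerance = 1e-9)
  expect_identical(observe_parallel(0, port), 0)
  # strict monotonicity of the observed coordinate
  xs <- seq(-1.5, 1.5, length.out = 41)
  expect_true(all(diff(observe_parallel(xs, port)) > 0))
  # magnification: underwater coordinates are inflated
  expect_true(all(abs(observe_parallel(xs, port)) >= abs(xs)))
  expect_error(correct_parallel(1e6, port), class = "fishstereo_beyond_tir")
})

test_that("inverse pairs round-trip to 1e-9 mm for all three models", {
  set.seed(99)
  port <- fig11_port()
  port_t <- fig11_port(tilt_rad = 2 * pi / 180)
  n <- 500
  x_r <- runif(n, -4, 4)
  expect_equal(observe_single(correct_single(x_r, port), port), x_r,
               tolerance = 1e-9)
  expect_equal(observe_parallel(correct_parallel(x_r, port), port), x_r,
               tolerance = 1e-9)
  expect_equal(correct_tilted(observe_tilted(
    correct_tilted(x_r, port_t), port_t), port_t),
    correct_tilted(x_r, port_t), tolerance = 1e-9)
  x_a <- runif(n, -1.6, 1.6)
  expect_equal(correct_parallel(observe_parallel(x_a, port), port), x_a,
               tolerance = 1e-9)
  expect_equal(observe_tilted(correct_tilted(
    observe_tilted(x_a, port_t), port_t), port_t),
    observe_tilted(x_a, port_t), tolerance = 1e-9)
})

test_that("model limit chain holds", {
  port <- fig11_port()
  xs <- seq(-2, 2, length.out = 21)
  # tilted with zero tilt is the parallel model
  expect_equal(correct_tilted(xs, port), correct_parallel(xs, port),
               tolerance = 1e-12)
  expect_equal(observe_tilted(xs / 2, port), observe_parallel(xs / 2, port),
               tolerance = 1e-12)
  # zero glass thickness collapses the slab onto the single-interface model
  port0 <- flat_port(d_mm = 3, T_mm = 0, n_air = 1, n_glass = 1.6,
                     n_water = 1.33)
  expect_equal(correct_parallel(xs, port0), correct_single(xs, port0),
               tolerance = 1e-9)
  # matched indices make refraction a no-op
  port_id <- flat_port(d_mm = 3, T_mm = 0, n_air = 1, n_glass = 1.6,
                       n_water = 1)
  expect_equal(correct_single(xs, port_id), xs, tolerance = 1e-12)
  # tilted correction approaches parallel monotonically as the tilt shrinks
  x0 <- 0.8
  tilts <- c(4, 2, 1, 0.5) * pi / 180
  gaps <- vapply(tilts, function(b) {
    abs(correct_tilted(x0, fig11_port(tilt_rad = b)) -
          correct_parallel(x0, fig11_port()))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[length(gaps)], gaps[1])
})

test_that("tilted model rejects impossible geometry", {
  port_bad <- flat_port(d_mm = 3, T_mm = 2.999, tilt_rad = 0.4)
  expect_error(correct_tilted(0.5, port_bad), class = "fishstereo_geometry")
})

test_that("magnification ratio behaves like pincushion distortion", {
  port <- fig11_port()
  # the analytic small-angle limit is the index ratio n_water / n_air
  expect_equal(magnification_ratio(1e-8, port, "single"), 1.33,
               tolerance = 1e-9)
  alphas <- seq(1e-4, fishstereo:::alpha_tir(port) - 1e-4, length.out = 200)
  rs <- magnification_ratio(alphas, port, "single")
  rp <- magnification_ratio(alphas, port, "parallel")
  expect_true(all(diff(rs) > 0))
  expect_true(all(diff(rp) > 0))
  # keeping the slab in the model lowers the magnification at every angle
  expect_true(all(rp < rs))
  expect_error(magnification_ratio(1.5, port, "single"),
               class = "fishstereo_error")
})

test_that("correct_keypoints undoes the rendered refraction", {
  K <- camera_intrinsics(f_mm = 3, dx_mm = 0.003, dy_mm = 0.003,
                         u0 = 320, v0 = 240)
  port <- default_flat_port(K)
  # keypoint at the principal point is an axial ray: unchanged
  kps0 <- make_kps(u = rep(320, 9), v = rep(240, 9))
  out0 <- correct_keypoints(kps0, K, port, "parallel")
  expect_equal(out0$points, kps0$points)

  set.seed(21)
  u <- runif(9, 40, 600); v <- runif(9, 30, 450)
  kps_air <- make_kps(u = u, v = v)
  # forward-render the underwater observation of each keypoint, then correct
  obs <- kps_air
  for (i in 1:9) {
    m <- pixel_to_metric(c(u[i], v[i]), K)
    r <- sqrt(sum(m^2))
    m_uw <- m * observe_parallel(r, port) / r
    obs$points[i, c("u", "v")] <- fishstereo:::metric_to_pixel(m_uw, K)
  }
  corr <- correct_keypoints(obs, K, port, "parallel")
  expect_equal(corr$points[, c("u", "v")], kps_air$points[, c("u", "v")],
               tolerance = 1e-6)
  # azimuth about the principal point is preserved
  az <- function(p) atan2(p[, "v"] - 240, p[, "u"] - 320)
  expect_equal(az(corr$points), az(obs$points), tolerance = 1e-9)
  # invisible keypoints pass through untouched
  vis <- rep(1, 9); vis[4] <- 0
  kps_inv <- make_kps(u = u, v = v, visibility = vis)
  out_inv <- correct_keypoints(kps_inv, K, port, "parallel")
  expect_equal(out_inv$points[4, ], kps_inv$points[4, ])
})
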