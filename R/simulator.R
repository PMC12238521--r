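#' Default synthetic stereo rig
#'
#' Mirrors the tank experiment's geometry: 3 mm lenses on a 3 um pixel
#' pitch, 640 x 480 images, a 60 mm baseline with parallel optical axes,
#' and flat ports with 2.8 mm glass at the focal point
#' (indices air/glass/water = 1 / 1.6 / 1.33). The world frame is the
#' left-camera frame. The baseline and relative pose are stated assumptions
#' of the simulator, not measured values.
#'
#' @param baseline_mm stereo baseline in mm (default 60).
#' @param model refraction model the ports are rendered with (stored on the
#'   rig for bookkeeping; operations take the model explicitly).
#' @param tilt_rad port tilt in radians (default 0).
#' @param k1,k2 lens distortion for both cameras (default 0).
#' @return A [stereo_rig()].
#' @export
default_stereo_rig <- function(baseline_mm = 60, model = "parallel",
                               tilt_rad = 0, k1 = 0, k2 = 0) {
  K <- camera_intrinsics(f_mm = 3, dx_mm = 0.003, dy_mm = 0.003,
                         u0 = 320, v0 = 240, k1 = k1, k2 = k2)
  port <- flat_port(d_mm = K$f_mm, T_mm = 2.8, tilt_rad = tilt_rad)
  rig <- stereo_rig(
    left = list(K = K, ext = camera_extrinsics(), port = port),
    right = list(K = K,
                 ext = camera_extrinsics(t = c(-baseline_mm, 0, 0)),
                 port = port),
    image_size = c(640, 480))
  rig$model <- model
  rig
}

# body-plan template on a unit mouth-to-tail axis (x from mouth at 0 to the
# tail-fin midpoint at 1), y dorsal up, z lateral; proportions are generic
# grouper anatomy
fish_template <- function() {
  matrix(c(
    0.00,  0.000,  0.000,   # mouth
    0.10,  0.040,  0.015,   # eye
    0.35,  0.180,  0.000,   # dorsal_fin1 (anterior end of dorsal fin)
    0.62,  0.150,  0.000,   # dorsal_fin2 (posterior end)
    1.00,  0.080,  0.000,   # tail_fin1 (top of tail fin)
    1.00, -0.080,  0.000,   # tail_fin2 (bottom)
    0.68, -0.120,  0.000,   # anal_fin
    0.85,  0.100,  0.000,   # top_fin
    0.30, -0.140, -0.015),  # pelvic_fin
    ncol = 3, byrow = TRUE,
    dimnames = list(FISH_KEYPOINT_NAMES, c("x", "y", "z")))
}

tail_rule_point <- function(pts, tail_rule = "midpoint") {
  switch(tail_rule,
    midpoint = (pts["tail_fin1", ] + pts["tail_fin2", ]) / 2,
    tail_fin1 = pts["tail_fin1", ],
    tail_fin2 = pts["tail_fin2", ])
}

#' Sample a 3D fish keypoint configuration
#'
#' Places the nine landmarks by scaling a fixed anatomical template to the
#' requested body length, bending the posterior half by `pose$bend`
#' (radians, about the dorsal axis at mid-body), adding seeded jitter of at
#' most 2% of the length, and applying the rigid pose
#' (yaw/pitch/roll, radians). After jitter and bend the configuration is
#' rescaled about the mouth so the mouth-to-tail distance (tail-fin
#' midpoint) equals `length_mm` exactly; the rigid pose preserves all
#' pairwise distances.
#'
#' @param length_mm body length in mm, in `[50, 2000]`.
#' @param pose list with elements `yaw`, `pitch`, `roll`, `bend` (radians,
#'   all default 0).
#' @param seed integer seed; identical seeds give identical coordinates.
#' @return 9 x 3 matrix of keypoint coordinates in the fish frame
#'   (mouth at the origin before pose), mm.
#' @export
sample_fish_keypoints <- function(length_mm, pose = list(), seed = 1L) {
  fs_assert(length_mm >= 50 && length_mm <= 2000,
            "length_mm must lie in [50, 2000]")
  pose <- utils::modifyList(list(yaw = 0, pitch = 0, roll = 0, bend = 0), pose)
  pts <- fish_template()
  if (pose$bend != 0) {
    rear <- pts[, "x"] > 0.5
    Rb <- rot_y(pose$bend)
    pivot <- c(0.5, 0, 0)
    pts[rear, ] <- t(Rb %*% (t(pts[rear, , drop = FALSE]) - pivot) + pivot)
  }
  jitter <- with_seed(seed, matrix(stats::runif(27, -0.02, 0.02), 9, 3))
  jitter[1, ] <- 0   # keep the mouth landmark exact
  pts <- pts + jitter
  # enforce the exact mouth-to-tail length, scaling about the mouth
  mouth <- pts["mouth", ]
  span <- sqrt(sum((tail_rule_point(pts) - mouth)^2))
  pts <- sweep(pts, 2, mouth) / span * length_mm
  R <- euler_rotation(pose$yaw, pose$pitch, pose$roll)
  pts <- t(R %*% t(pts))
  dimnames(pts) <- list(FISH_KEYPOINT_NAMES, c("x", "y", "z"))
  pts
}

in_frame <- function(pix, image_size) {
  pix[1] >= 0 && pix[1] <= image_size[1] - 1 &&
    pix[2] >= 0 && pix[2] <= image_size[2] - 1
}

# project world keypoints into one camera: returns air-equivalent pixels and
# refraction-distorted underwater observations
render_view <- function(pts_world, cam, image_size, model) {
  n <- nrow(pts_world)
  air <- matrix(0, n, 3, dimnames = list(rownames(pts_world), c("u", "v", "visibility")))
  obs <- air
  for (i in seq_len(n)) {
    pc <- world_to_camera(pts_world[i, ], cam$ext)
    if (pc[3] <= 0)
      fs_stop("fish keypoint behind the camera", "fishstereo_behind_camera")
    pix <- camera_to_pixel(pc, cam$K)
    vis_air <- in_frame(pix, image_size)
    air[i, ] <- c(pix, as.numeric(vis_air))
    m <- pixel_to_metric(pix, cam$K)
    uw <- tryCatch(
      metric_to_pixel(apply_refraction_metric(m, cam$port, model, "observe"),
                      cam$K),
      fishstereo_beyond_tir = function(e) NULL)
    if (is.null(uw)) {
      obs[i, ] <- c(pix, 0)
    } else {
      obs[i, ] <- c(uw, as.numeric(vis_air && in_frame(uw, image_size)))
    }
  }
  list(air = air, obs = obs)
}

kp_bbox <- function(pts, pad = 5) {
  vis <- pts[, "visibility"] == 1
  if (!any(vis)) return(c(0, 0, 0, 0))
  u <- pts[vis, "u"]; v <- pts[vis, "v"]
  c(min(u) - pad, min(v) - pad,
    diff(range(u)) + 2 * pad, diff(range(v)) + 2 * pad)
}

#' Render a synthetic refractive stereo scene
#'
#' Projects ground-truth 3D fish keypoints into both cameras twice: once as
#' a plain pinhole projection (the "equivalent air" image, the oracle for
#' refraction correction) and once through the forward flat-port refraction
#' map, with optional Gaussian pixel noise on the underwater observations.
#' Keypoints falling outside the frame or beyond the TIR-limited field are
#' marked invisible.
#'
#' @param fish_list list of 9 x 3 world-frame keypoint matrices (mm), e.g.
#'   from [sample_fish_keypoints()] plus a translation.
#' @param rig a [stereo_rig()].
#' @param noise_sigma_px standard deviation of isotropic pixel noise added
#'   to the underwater observations (default 0).
#' @param seed integer seed for the noise draws.
#' @param model refraction model used for rendering (defaults to the rig's).
#' @param tail_rule rule defining the true length (default `"midpoint"`).
#' @return list of class `synthetic_scene`: `rig`, `fish` (list with
#'   `points3d`, `true_length_mm`), `observations` and `air_equiv` (each a
#'   list `left`/`right` of [fish_keypoints()] lists), `seed`.
#' @export
render_scene <- function(fish_list, rig, noise_sigma_px = 0, seed = 1L,
                         model = NULL, tail_rule = "midpoint") {
  stopifnot(inherits(rig, "stereo_rig"))
  if (is.null(model)) model <- if (is.null(rig$model)) "parallel" else rig$model
  add_noise <- function(view) {
    if (noise_sigma_px > 0) {
      noise <- matrix(stats::rnorm(18, 0, noise_sigma_px), 9, 2)
      view$obs[, c("u", "v")] <- view$obs[, c("u", "v")] + noise
    }
    view
  }
  views <- with_seed(seed, {
    lapply(fish_list, function(pts) {
      list(lv = add_noise(render_view(pts, rig$left, rig$image_size, model)),
           rv = add_noise(render_view(pts, rig$right, rig$image_size, model)))
    })
  })
  fish <- lapply(fish_list, function(pts) {
    list(points3d = pts,
         true_length_mm = sqrt(sum((tail_rule_point(pts, tail_rule) -
                                      pts["mouth", ])^2)))
  })
  as_kps <- function(m) fish_keypoints(m, bbox = kp_bbox(m))
  structure(list(
    rig = rig,
    fish = fish,
    observations = list(
      left = lapply(views, function(v) as_kps(v$lv$obs)),
      right = lapply(views, function(v) as_kps(v$rv$obs))),
    air_equiv = list(
      left = lapply(views, function(v) as_kps(v$lv$air)),
      right = lapply(views, function(v) as_kps(v$rv$air))),
    model = model, seed = seed),
    class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %d fish, model '%s', seed %d\n",
              length(x$fish), x$model, x$seed))
  invisible(x)
}

#' Simulate a tank scene of swimming fish
#'
#' Draws fish lengths, poses and positions emulating the tank experiment
#' (default: lengths 80-105 mm, working range 300-700 mm in front of the
#' rig) and renders the stereo observations with [render_scene()]. Fish are
#' placed so that all keypoints project inside both frames.
#'
#' @param n_fish number of fish.
#' @param rig a [stereo_rig()] (default [default_stereo_rig()]).
#' @param length_range_mm body-length range, mm.
#' @param z_range_mm working-distance range, mm.
#' @param noise_sigma_px pixel noise on the observations (default 0).
#' @param seed integer seed.
#' @param model refraction model for rendering.
#' @return A `synthetic_scene` (see [render_scene()]).
#' @export
simulate_fish_scene <- function(n_fish = 3, rig = default_stereo_rig(),
                                length_range_mm = c(80, 105),
                                z_range_mm = c(300, 700),
                                noise_sigma_px = 0, seed = 1L,
                                model = NULL) {
  # conservative half-field tangents of the *underwater* image (the observed
  # coordinates are magnified ~1.33-1.45x relative to the air image)
  half_tan_x <- 0.20
  half_tan_y <- 0.15
  base_x <- -as.numeric(crossprod(rig$right$ext$R, rig$right$ext$t))[1] / 2
  if (is.null(model)) model <- if (is.null(rig$model)) "parallel" else rig$model
  fish_list <- with_seed(seed, {
    lapply(seq_len(n_fish), function(i) {
      for (attempt in 1:50) {
        len <- stats::runif(1, length_range_mm[1], length_range_mm[2])
        pose <- list(yaw = stats::runif(1, -0.3, 0.3),
                     pitch = stats::runif(1, -0.15, 0.15),
                     roll = stats::runif(1, -0.15, 0.15),
                     bend = stats::runif(1, -0.15, 0.15))
        kp_seed <- floor(stats::runif(1, 1, 2^30))
        z <- stats::runif(1, z_range_mm[1], z_range_mm[2])
        # both frusta constrain x to an interval centered between the cameras
        z <- max(z, (abs(base_x) + len / 2 + 5) / half_tan_x)
        sx <- half_tan_x * z - len / 2 - abs(base_x)
        sy <- max(half_tan_y * z - 0.35 * len, 0)
        ctr <- c(base_x + stats::runif(1, -1, 1) * max(sx, 0),
                 stats::runif(1, -1, 1) * sy,
                 z)
        pts <- sample_fish_keypoints(len, pose, seed = kp_seed)
        pts <- sweep(pts, 2, ctr - colMeans(pts), "+")
        ok <- tryCatch({
          lv <- render_view(pts, rig$left, rig$image_size, model)
          rv <- render_view(pts, rig$right, rig$image_size, model)
          all(lv$obs[, "visibility"] == 1) && all(rv$obs[, "visibility"] == 1)
        }, error = function(e) FALSE)
        if (ok) return(pts)
      }
      fs_stop("could not place a fish inside both frusta",
              "fishstereo_placement")
    })
  })
  render_scene(fish_list, rig, noise_sigma_px = noise_sigma_px,
               seed = seed + 1L, model = model)
}

#' Synthetic checkerboard views for calibration tests
#'
#' Renders a planar checkerboard (8 x 6 inner corners, 25 mm squares by
#' default) through a known intrinsic matrix under a deterministic set of
#' distinct poses (pairwise relative rotation >= 10 degrees), with optional
#' corner noise.
#'
#' @param K_true the ground-truth [camera_intrinsics()].
#' @param n_views number of views (>= 3 for downstream calibration).
#' @param noise_sigma_px Gaussian corner noise, px (default 0).
#' @param seed integer seed for the noise.
#' @param board_size inner-corner grid `(nx, ny)`.
#' @param square_mm square side length, mm.
#' @return list of [planar_correspondences()].
#' @export
make_checkerboard_views <- function(K_true, n_views = 5, noise_sigma_px = 0,
                                    seed = 1L, board_size = c(8, 6),
                                    square_mm = 25) {
  grid <- as.matrix(expand.grid(
    X_mm = (seq_len(board_size[1]) - 1) * square_mm,
    Y_mm = (seq_len(board_size[2]) - 1) * square_mm))
  A <- intrinsic_matrix(K_true)
  axes <- list(c(1, 0.2, 0), c(0.1, 1, 0), c(1, -1, 0.2),
               c(-1, 0.3, 0), c(0.4, -1, 0.1), c(1, 1, 0))
  with_seed(seed, {
    lapply(seq_len(n_views), function(i) {
      ax <- axes[[(i - 1) %% length(axes) + 1]]
      ax <- ax / sqrt(sum(ax^2))
      ang <- deg2rad(12 + 11 * (i - 1) %% 40)
      # Rodrigues rotation about ax by ang
      Kx <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                   3, 3, byrow = TRUE)
      R <- diag(3) + sin(ang) * Kx + (1 - cos(ang)) * Kx %*% Kx
      t <- c(-90 + 12 * i, -60 + 8 * i, 420 + 45 * i)
      P <- A %*% cbind(R[, 1:2], t)
      pix <- apply_homography(P, grid)
      if (noise_sigma_px > 0)
        pix <- pix + matrix(stats::rnorm(length(pix), 0, noise_sigma_px),
                            ncol = 2)
      planar_correspondences(grid, pix, view_id = i)
    })
  })
}
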