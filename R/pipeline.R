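#' Read a stereo calibration file
#'
#' YAML or JSON (by extension) with one entry per camera id (`left`,
#' `right`), each holding `intrinsics` (`f_mm`, `dx_mm`, `dy_mm`, `skew`,
#' `u0`, `v0`, `k1`, `k2`), `extrinsics` (`R` row-major 9-vector, `t`
#' 3-vector) and optionally `port` (`d_mm`, `T_mm`, `n_air`, `n_glass`,
#' `n_water`, `tilt_deg`). A top-level `port` applies to both cameras
#' (shared enclosure, the default configuration); `image_size` is
#' `(width, height)`.
#'
#' @param path calibration file path.
#' @return A [stereo_rig()].
#' @export
read_calibration <- function(path) {
  fs_assert(file.exists(path), sprintf("calibration file not found: %s", path),
            "fishstereo_io")
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  parse_port <- function(p, f_mm) {
    if (is.null(p)) return(flat_port(d_mm = f_mm, T_mm = 2.8))
    flat_port(d_mm = if (is.null(p$d_mm)) f_mm else p$d_mm,
              T_mm = if (is.null(p$T_mm)) 2.8 else p$T_mm,
              n_air = if (is.null(p$n_air)) 1.0 else p$n_air,
              n_glass = if (is.null(p$n_glass)) 1.6 else p$n_glass,
              n_water = if (is.null(p$n_water)) 1.33 else p$n_water,
              tilt_rad = deg2rad(if (is.null(p$tilt_deg)) 0 else p$tilt_deg))
  }
  parse_cam <- function(cam) {
    fs_assert(!is.null(cam$intrinsics) && !is.null(cam$extrinsics),
              "camera entry needs intrinsics and extrinsics", "fishstereo_schema")
    ii <- cam$intrinsics
    K <- camera_intrinsics(
      f_mm = ii$f_mm, dx_mm = ii$dx_mm, dy_mm = ii$dy_mm,
      skew = if (is.null(ii$skew)) 0 else ii$skew,
      u0 = ii$u0, v0 = ii$v0,
      k1 = if (is.null(ii$k1)) 0 else ii$k1,
      k2 = if (is.null(ii$k2)) 0 else ii$k2)
    ext <- camera_extrinsics(
      R = matrix(as.numeric(unlist(cam$extrinsics$R)), 3, 3, byrow = TRUE),
      t = as.numeric(unlist(cam$extrinsics$t)))
    port <- parse_port(if (!is.null(cam$port)) cam$port else cfg$port, K$f_mm)
    list(K = K, ext = ext, port = port)
  }
  fs_assert(!is.null(cfg$left) && !is.null(cfg$right),
            "calibration file needs 'left' and 'right' cameras",
            "fishstereo_schema")
  image_size <- if (is.null(cfg$image_size)) c(640, 480) else
    as.numeric(unlist(cfg$image_size))
  stereo_rig(parse_cam(cfg$left), parse_cam(cfg$right), image_size = image_size)
}

#' Write a stereo calibration file
#'
#' Inverse of [read_calibration()] (YAML).
#'
#' @param rig a [stereo_rig()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(rig, path) {
  dump_cam <- function(cam) {
    list(intrinsics = list(f_mm = cam$K$f_mm, dx_mm = cam$K$dx_mm,
                           dy_mm = cam$K$dy_mm, skew = cam$K$skew,
                           u0 = cam$K$u0, v0 = cam$K$v0,
                           k1 = cam$K$k1, k2 = cam$K$k2),
         extrinsics = list(R = as.numeric(t(cam$ext$R)), t = cam$ext$t),
         port = list(d_mm = cam$port$d_mm, T_mm = cam$port$T_mm,
                     n_air = cam$port$n_air, n_glass = cam$port$n_glass,
                     n_water = cam$port$n_water,
                     tilt_deg = rad2deg(cam$port$tilt_rad)))
  }
  yaml::write_yaml(list(left = dump_cam(rig$left), right = dump_cam(rig$right),
                        image_size = rig$image_size), path, precision = 15)
  invisible(path)
}

scene_to_annotation_set <- function(scene, side) {
  kps_list <- scene$observations[[side]]
  images <- data.frame(id = 1L, file_name = sprintf("%s.png", side),
                       width = scene$rig$image_size[1],
                       height = scene$rig$image_size[2])
  annotations <- lapply(seq_along(kps_list), function(i) {
    list(id = i, image_id = 1L, keypoints = kps_list[[i]])
  })
  names(annotations) <- as.character(seq_along(kps_list))
  structure(list(images = images, annotations = annotations,
                 categories = fish_category()),
            class = "annotation_set")
}

#' Export a synthetic scene for the measurement pipeline
#'
#' Writes the per-view keypoint observations as COCO-dialect JSON
#' (`left.json`, `right.json`), the rig and port configuration
#' (`rig.yaml`), the ground truth (`truth.csv`: fish_id, length_mm) and the
#' full 3D ground truth (`truth.json`).
#'
#' @param scene a `synthetic_scene` from [render_scene()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_annotations(scene_to_annotation_set(scene, "left"),
                    file.path(dir, "left.json"))
  write_annotations(scene_to_annotation_set(scene, "right"),
                    file.path(dir, "right.json"))
  write_calibration(scene$rig, file.path(dir, "rig.yaml"))
  truth <- data.frame(
    fish_id = seq_along(scene$fish),
    length_mm = vapply(scene$fish, function(f) f$true_length_mm, numeric(1)))
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = scene$seed, model = scene$model,
         fish = lapply(scene$fish, function(f) {
           list(true_length_mm = f$true_length_mm,
                points3d = as.data.frame(f$points3d))
         })),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the end-to-end measurement pipeline
#'
#' Reads paired left/right keypoint annotation files and a calibration
#' file, refraction-corrects and triangulates every fish (annotations are
#' paired by id across the two files), and writes a measurement CSV. When a
#' ground-truth CSV (`fish_id`, `length_mm`) is supplied, relative-error
#' statistics are computed and written as JSON.
#'
#' @param config list (or path to a YAML file) with entries `calibration`,
#'   `left`, `right`, optional `truth`, `out_csv`, `out_json`, `model`
#'   (`"single"`, `"parallel"`, `"tilted"`, or `"none"` to skip
#'   correction), `tail_rule`.
#' @return list with `measurements` (data.frame), `stats` (list with
#'   `re_list` and `mrpe`, or NULL without ground truth).
#' @export
run_measurement <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(
    list(model = "parallel", tail_rule = "midpoint",
         truth = NULL, out_csv = NULL, out_json = NULL), config)
  fs_assert(config$model %in% c("single", "parallel", "tilted", "none"),
            "model must be one of single, parallel, tilted, none")
  rig <- read_calibration(config$calibration)
  left <- read_annotations(config$left)
  right <- read_annotations(config$right)
  ids <- intersect(names(left$annotations), names(right$annotations))
  fs_assert(length(ids) > 0, "no annotation ids shared by the two views",
            "fishstereo_schema")
  rows <- lapply(ids, function(id) {
    m <- measure_fish(left$annotations[[id]]$keypoints,
                      right$annotations[[id]]$keypoints,
                      rig, model = config$model, tail_rule = config$tail_rule)
    p <- m$points3d
    row <- data.frame(fish_id = as.integer(id), length_mm = m$length_mm,
                      residual_px = mean(m$residuals_px, na.rm = TRUE))
    for (nm in FISH_KEYPOINT_NAMES) {
      row[[paste0(nm, "_X")]] <- p[nm, "X"]
      row[[paste0(nm, "_Y")]] <- p[nm, "Y"]
      row[[paste0(nm, "_Z")]] <- p[nm, "Z"]
    }
    row
  })
  measurements <- do.call(rbind, rows)
  measurements <- measurements[order(measurements$fish_id), ]
  stats <- NULL
  if (!is.null(config$truth)) {
    truth <- utils::read.csv(config$truth)
    fs_assert(all(c("fish_id", "length_mm") %in% names(truth)),
              "truth CSV needs columns fish_id, length_mm", "fishstereo_schema")
    merged <- merge(measurements[, c("fish_id", "length_mm")], truth,
                    by = "fish_id", suffixes = c("_est", "_true"))
    re_list <- relative_error(merged$length_mm_est, merged$length_mm_true)
    stats <- list(re_list = re_list, mrpe = mean(re_list))
  }
  if (!is.null(config$out_csv)) {
    out <- measurements
    num <- vapply(out, is.numeric, logical(1)) & names(out) != "fish_id"
    out[num] <- lapply(out[num], function(x) formatC(x, format = "f", digits = 6))
    utils::write.csv(out, config$out_csv, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(config$out_json) && !is.null(stats)) {
    jsonlite::write_json(stats, config$out_json, auto_unbox = TRUE, digits = NA)
  }
  list(measurements = measurements, stats = stats)
}

#' Measure every fish of a rendered scene in memory
#'
#' Convenience wrapper over [measure_fish()] for `synthetic_scene` objects,
#' returning estimated and true lengths side by side.
#'
#' @param scene a `synthetic_scene`.
#' @param model refraction model, or `"none"` to skip correction.
#' @param tail_rule tail point rule (default `"midpoint"`).
#' @return data.frame with `fish_id`, `length_mm`, `true_length_mm`,
#'   `re_pct`.
#' @export
measure_scene <- function(scene, model = NULL, tail_rule = "midpoint") {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (is.null(model)) model <- scene$model
  rows <- lapply(seq_along(scene$fish), function(i) {
    m <- measure_fish(scene$observations$left[[i]],
                      scene$observations$right[[i]],
                      scene$rig, model = model, tail_rule = tail_rule)
    data.frame(fish_id = i, length_mm = m$length_mm,
               true_length_mm = scene$fish[[i]]$true_length_mm,
               re_pct = relative_error(m$length_mm,
                                       scene$fish[[i]]$true_length_mm))
  })
  do.call(rbind, rows)
}
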