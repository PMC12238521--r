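#' The 9-keypoint fish schema
#'
#' Anatomical landmark names, in their fixed order: mouth, eye, anterior and
#' posterior ends of the dorsal fin, top and bottom of the tail fin, anal
#' fin, top fin, pelvic fin. These nine landmarks are present across nearly
#' all farmed fish species and summarize the fish's posture.
#'
#' @export
FISH_KEYPOINT_NAMES <- c("mouth", "eye", "dorsal_fin1", "dorsal_fin2",
                         "tail_fin1", "tail_fin2", "anal_fin", "top_fin",
                         "pelvic_fin")

#' Fish keypoints in one view
#'
#' Holds the nine named keypoints of a single fish in one image, each as
#' `(u, v, visibility)` with visibility in `{0, 1}` (1 = visible), plus the
#' fish bounding box `(x, y, w, h)` in pixels.
#'
#' @param points 9 x 3 numeric matrix with columns `u`, `v`, `visibility`;
#'   row order (or row names) must follow [FISH_KEYPOINT_NAMES].
#' @param bbox optional length-4 numeric `(x, y, w, h)` in px.
#' @return An object of class `fish_keypoints`.
#' @export
fish_keypoints <- function(points, bbox = NULL) {
  points <- as.matrix(points)
  fs_assert(nrow(points) == 9L && ncol(points) == 3L,
            "keypoints must form a 9 x 3 matrix (u, v, visibility)",
            "fishstereo_keypoint_count")
  colnames(points) <- c("u", "v", "visibility")
  if (is.null(rownames(points))) {
    rownames(points) <- FISH_KEYPOINT_NAMES
  } else {
    fs_assert(identical(rownames(points), FISH_KEYPOINT_NAMES),
              "keypoint rows must follow the fixed 9-name order",
              "fishstereo_schema")
  }
  fs_assert(all(points[, "visibility"] %in% c(0, 1)),
            "visibility flags must be 0 or 1", "fishstereo_schema")
  vis <- points[, "visibility"] == 1
  fs_assert(all(is.finite(points[vis, c("u", "v")])),
            "visible keypoints must have finite coordinates")
  if (!is.null(bbox)) {
    bbox <- as.numeric(bbox)
    fs_assert(length(bbox) == 4L && all(is.finite(bbox)) && all(bbox[3:4] >= 0),
              "bbox must be (x, y, w, h) with non-negative size")
  }
  structure(list(points = points, bbox = bbox), class = "fish_keypoints")
}

#' @export
print.fish_keypoints <- function(x, ...) {
  cat(sprintf("fish_keypoints: %d/9 visible\n", sum(x$points[, "visibility"])))
  print(round(x$points, 3))
  invisible(x)
}

#' Bounding-box diagonal, the NME normalizer
#'
#' @param kps a [fish_keypoints()] object with a bbox.
#' @return The diagonal length of the bounding box in px.
#' @export
bbox_diagonal <- function(kps) {
  fs_assert(!is.null(kps$bbox), "keypoints carry no bounding box")
  sqrt(kps$bbox[3]^2 + kps$bbox[4]^2)
}

# ---- COCO-dialect annotation I/O ----

#' Read a COCO-style fish keypoint annotation file
#'
#' Parses the JSON dialect used for fish keypoint datasets: top-level
#' `images`, `annotations`, `categories`; each annotation holds a flat
#' 27-element `keypoints` array (x, y, v for each of the 9 landmarks), a
#' `bbox`, `image_id` and `id`. Visibility 2 (standard COCO "visible") is
#' mapped to 1; this package writes `{0, 1}` flags.
#'
#' @param path path to the JSON file.
#' @return A list of class `annotation_set` with elements `images`
#'   (data.frame id, file_name, width, height), `annotations` (named list of
#'   `list(id, image_id, keypoints)`), and `categories`.
#' @export
read_annotations <- function(path) {
  fs_assert(file.exists(path), sprintf("annotation file not found: %s", path),
            "fishstereo_io")
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (key in c("images", "annotations"))
    fs_assert(!is.null(doc[[key]]),
              sprintf("annotation file missing top-level '%s'", key),
              "fishstereo_schema")
  images <- do.call(rbind, lapply(doc$images, function(im) {
    fs_assert(!is.null(im$id), "image record missing id", "fishstereo_schema")
    data.frame(id = as.integer(im$id),
               file_name = if (is.null(im$file_name)) NA_character_ else im$file_name,
               width = if (is.null(im$width)) NA_real_ else as.numeric(im$width),
               height = if (is.null(im$height)) NA_real_ else as.numeric(im$height),
               stringsAsFactors = FALSE)
  }))
  annotations <- lapply(doc$annotations, function(an) {
    id <- an$id
    fs_assert(!is.null(id) && !is.null(an$image_id),
              "annotation record missing id or image_id", "fishstereo_schema")
    fs_assert(as.integer(an$image_id) %in% images$id,
              sprintf("annotation %s references unknown image_id %s",
                      id, an$image_id), "fishstereo_schema")
    kp <- as.numeric(unlist(an$keypoints))
    if (length(kp) != 27L)
      fs_stop(sprintf("annotation %s: expected 9 keypoints (27 values), got %d values",
                      id, length(kp)), "fishstereo_keypoint_count")
    pts <- matrix(kp, ncol = 3, byrow = TRUE,
                  dimnames = list(FISH_KEYPOINT_NAMES, c("u", "v", "visibility")))
    pts[, "visibility"] <- ifelse(pts[, "visibility"] >= 1, 1, 0)
    bbox <- if (!is.null(an$bbox)) as.numeric(unlist(an$bbox)) else NULL
    list(id = as.integer(id), image_id = as.integer(an$image_id),
         keypoints = fish_keypoints(pts, bbox = bbox))
  })
  names(annotations) <- vapply(annotations, function(a) as.character(a$id), "")
  structure(list(images = images, annotations = annotations,
                 categories = fish_category()),
            class = "annotation_set")
}

fish_category <- function() {
  list(id = 1L, name = "fish",
       keypoints = as.list(FISH_KEYPOINT_NAMES),
       skeleton = list(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 8L),
                       c(8L, 5L), c(5L, 6L), c(6L, 7L), c(7L, 9L),
                       c(9L, 1L)))
}

#' Write a COCO-style fish keypoint annotation file
#'
#' Inverse of [read_annotations()]; the round trip is lossless on the
#' retained fields (images, keypoint arrays, bboxes, ids).
#'
#' @param set an `annotation_set` as returned by [read_annotations()], or a
#'   list with the same shape.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(set, path) {
  images <- lapply(seq_len(nrow(set$images)), function(i) {
    im <- set$images[i, ]
    out <- list(id = im$id)
    if (!is.na(im$file_name)) out$file_name <- im$file_name
    if (!is.na(im$width)) out$width <- im$width
    if (!is.na(im$height)) out$height <- im$height
    out
  })
  annotations <- lapply(set$annotations, function(an) {
    pts <- an$keypoints$points
    out <- list(id = an$id, image_id = an$image_id, category_id = 1L,
                keypoints = as.numeric(t(pts)),
                num_keypoints = sum(pts[, "visibility"]))
    if (!is.null(an$keypoints$bbox)) out$bbox <- an$keypoints$bbox
    out
  })
  doc <- list(images = images,
              annotations = unname(annotations),
              categories = list(fish_category()))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- evaluation metrics ----

#' Normalized mean error of predicted keypoints
#'
#' \deqn{NME = \frac{1}{N} \sum_{i=1}^{N}
#'   \frac{\lVert p_i - \hat p_i \rVert_2}{d}}
#' where the sum runs over the keypoints visible in both sets and `d` is the
#' normalizer, conventionally the diagonal of the fish bounding box (see
#' [bbox_diagonal()]).
#'
#' @param truth,pred [fish_keypoints()] objects.
#' @param normalizer positive scalar, px.
#' @return Dimensionless mean normalized error.
#' @export
nme <- function(truth, pred, normalizer) {
  stopifnot(inherits(truth, "fish_keypoints"), inherits(pred, "fish_keypoints"))
  if (!is.numeric(normalizer) || normalizer <= 0)
    fs_stop("normalizer must be > 0", "fishstereo_zero_normalizer")
  joint <- truth$points[, "visibility"] == 1 & pred$points[, "visibility"] == 1
  if (!any(joint))
    fs_stop("no keypoints visible in both sets", "fishstereo_no_common_visible")
  d <- truth$points[joint, c("u", "v"), drop = FALSE] -
    pred$points[joint, c("u", "v"), drop = FALSE]
  mean(sqrt(rowSums(d^2))) / normalizer
}

#' Intersection-over-union of two boxes
#'
#' @param a,b boxes as `(x, y, w, h)`.
#' @return IoU in `[0, 1]`.
#' @export
bbox_iou <- function(a, b) {
  ix <- max(0, min(a[1] + a[3], b[1] + b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[2] + a[4], b[2] + b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  union <- a[3] * a[4] + b[3] * b[4] - inter
  if (union <= 0) return(0)
  inter / union
}

#' Average precision over IoU thresholds
#'
#' Greedy IoU matching of predicted boxes to ground-truth boxes per
#' threshold (predictions visited in decreasing score; ties broken by
#' highest IoU, then lowest prediction index), followed by all-point
#' precision-recall integration. Reports AP at each threshold and their
#' mean, the conventional AP at IoU 0.50:0.05:0.95.
#'
#' @param preds data.frame of predictions with columns `image_id`, `x`, `y`,
#'   `w`, `h` and optionally `score` (defaults to 1).
#' @param truths data.frame of ground truths with columns `image_id`, `x`,
#'   `y`, `w`, `h`.
#' @param iou_thresholds IoU thresholds in `(0, 1]`.
#' @return list with `table` (data.frame threshold, ap) and `mean_ap`; with
#'   no ground truths both are NULL.
#' @export
evaluate_detection <- function(preds, truths,
                               iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  fs_assert(all(iou_thresholds > 0 & iou_thresholds <= 1),
            "IoU thresholds must lie in (0, 1]")
  if (is.null(truths) || nrow(truths) == 0)
    return(list(table = NULL, mean_ap = NULL))
  if (is.null(preds$score)) preds$score <- rep(1, nrow(preds))
  ap <- vapply(iou_thresholds, function(thr) {
    ap_at_threshold(preds, truths, thr)
  }, numeric(1))
  tab <- data.frame(threshold = iou_thresholds, ap = ap)
  list(table = tab, mean_ap = mean(ap))
}

ap_at_threshold <- function(preds, truths, thr) {
  n_truth <- nrow(truths)
  if (is.null(preds) || nrow(preds) == 0) return(0)
  ord <- order(-preds$score, seq_len(nrow(preds)))
  matched <- logical(n_truth)
  tp <- numeric(length(ord))
  for (k in seq_along(ord)) {
    p <- preds[ord[k], ]
    cand <- which(!matched & truths$image_id == p$image_id)
    if (length(cand) == 0) next
    ious <- vapply(cand, function(j) {
      bbox_iou(c(p$x, p$y, p$w, p$h),
               c(truths$x[j], truths$y[j], truths$w[j], truths$h[j]))
    }, numeric(1))
    best <- which.max(ious)
    if (ious[best] >= thr) {
      matched[cand[best]] <- TRUE
      tp[k] <- 1
    }
  }
  cum_tp <- cumsum(tp)
  recall <- cum_tp / n_truth
  precision <- cum_tp / seq_along(tp)
  # all-point interpolation: integrate the precision envelope over recall
  prec_env <- rev(cummax(rev(precision)))
  ap <- 0
  prev_r <- 0
  for (k in seq_along(recall)) {
    if (recall[k] > prev_r) {
      ap <- ap + (recall[k] - prev_r) * prec_env[k]
      prev_r <- recall[k]
    }
  }
  ap
}
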