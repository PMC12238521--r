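test_that("fish_keypoints enforces the 9-landmark schema", {
  kps <- make_kps()
  expect_s3_class(kps, "fish_keypoints")
  expect_identical(rownames(kps$points), FISH_KEYPOINT_NAMES)
  expect_error(fish_keypoints(matrix(0, 8, 3)),
               class = "fishstereo_keypoint_count")
  bad <- cbind(seq(9), seq(9), rep(2, 9))  # visibility must be binary
  expect_error(fish_keypoints(bad), class = "fishstereo_schema")
})

test_that("annotation JSON round trip is lossless", {
  set.seed(17)
  anns <- lapply(1:10, function(i) {
    u <- runif(9, 0, 640); v <- runif(9, 0, 480)
    vis <- rbinom(9, 1, 0.9)
    list(id = i, image_id = 1L,
         keypoints = fish_keypoints(cbind(u, v, vis),
                                    bbox = c(min(u), min(v),
                                             diff(range(u)), diff(range(v)))))
  })
  names(anns) <- as.character(1:10)
  set <- structure(list(
    images = data.frame(id = 1L, file_name = "tank.png",
                        width = 640, height = 480),
    annotations = anns, categories = fishstereo:::fish_category()),
    class = "annotation_set")
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(set, path)
  back <- read_annotations(path)
  expect_equal(back$images$file_name, "tank.png")
  expect_length(back$annotations, 10)
  for (id in names(anns)) {
    expect_equal(back$annotations[[id]]$keypoints$points,
                 anns[[id]]$keypoints$points)
    expect_equal(back$annotations[[id]]$keypoints$bbox,
                 anns[[id]]$keypoints$bbox)
  }
  # a second write of the parsed set is byte-identical
  path2 <- withr::local_tempfile(fileext = ".json")
  write_annotations(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed annotation files fail with named records", {
  doc <- list(
    images = list(list(id = 1, file_name = "a.png")),
    annotations = list(list(id = 7, image_id = 1,
                            keypoints = as.list(rep(0, 24)),  # 8 keypoints
                            bbox = c(0, 0, 10, 10))),
    categories = list())
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_annotations(path), regexp = "7",
               class = "fishstereo_keypoint_count")
  # COCO visibility 2 is accepted and mapped to 1
  doc$annotations[[1]]$keypoints <- as.list(rep(c(5, 5, 2), 9))
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  set <- read_annotations(path)
  expect_true(all(set$annotations[["7"]]$keypoints$points[, "visibility"] == 1))
})

test_that("nme follows its definition", {
  truth <- make_kps()
  expect_equal(nme(truth, truth, 100), 0)
  # one keypoint displaced by exactly the normalizer
  pred <- truth
  pred$points[3, "u"] <- pred$points[3, "u"] + 50
  expect_equal(nme(truth, pred, 50), 1 / 9)
  # homogeneity in the normalizer
  expect_equal(nme(truth, pred, 100), 1 / 18)
  expect_error(nme(truth, pred, 0), class = "fishstereo_zero_normalizer")
  none <- make_kps(visibility = rep(0, 9))
  expect_error(nme(none, pred, 50), class = "fishstereo_no_common_visible")
  # only jointly visible keypoints enter the mean
  vis <- rep(1, 9); vis[3] <- 0
  pred_inv <- make_kps(visibility = vis)
  pred_inv$points[, "u"] <- truth$points[, "u"]
  pred_inv$points[, "v"] <- truth$points[, "v"]
  pred_inv$points[3, "u"] <- 1e6   # hidden, must not contribute
  expect_equal(nme(truth, pred_inv, 50), 0)
})

test_that("nme is invariant under a shared rigid motion", {
  set.seed(23)
  truth <- make_kps(u = runif(9, 100, 500), v = runif(9, 100, 400))
  pred <- truth
  pred$points[, c("u", "v")] <- pred$points[, c("u", "v")] +
    matrix(rnorm(18, 0, 2), 9, 2)
  base <- nme(truth, pred, 120)
  th <- 0.7; Rz <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  move <- function(k) {
    k$points[, c("u", "v")] <- k$points[, c("u", "v")] %*% t(Rz) +
      matrix(c(30, -40), 9, 2, byrow = TRUE)
    k
  }
  expect_equal(nme(move(truth), move(pred), 120), base, tolerance = 1e-12)
})

test_that("detection AP matches IoU arithmetic", {
  truths <- data.frame(image_id = c(1, 1, 2),
                       x = c(10, 200, 50), y = c(10, 100, 60),
                       w = c(80, 60, 90), h = c(40, 50, 70))
  # perfect predictions give AP 1 at every threshold
  preds <- truths; preds$score <- c(0.9, 0.8, 0.95)
  ev <- evaluate_detection(preds, truths)
  expect_true(all(ev$table$ap == 1))
  expect_equal(ev$mean_ap, 1)
  # no predictions at all
  ev0 <- evaluate_detection(truths[0, ], truths)
  expect_true(all(ev0$table$ap == 0))
  # boxes shrunk to 40% of the area have IoU 0.4 < 0.5
  shrunk <- truths
  shrunk$w <- shrunk$w * 0.4
  shrunk$score <- 1
  ev4 <- evaluate_detection(shrunk, truths)
  expect_equal(ev4$table$ap[ev4$table$threshold == 0.5], 0)
  # AP is monotone non-increasing in the threshold
  set.seed(2)
  jit <- truths
  jit$x <- jit$x + runif(3, 0, 8); jit$w <- jit$w * runif(3, 0.8, 1)
  jit$score <- runif(3)
  evj <- evaluate_detection(jit, truths)
  expect_true(all(diff(evj$table$ap) <= 1e-12))
  # empty ground truth yields a null report
  expect_null(evaluate_detection(preds, truths[0, ])$mean_ap)
})

test_that("bbox_iou handles overlap and disjoint boxes", {
  a <- c(0, 0, 10, 10)
  expect_equal(bbox_iou(a, a), 1)
  expect_equal(bbox_iou(a, c(5, 0, 10, 10)), 50 / 150)
  expect_equal(bbox_iou(a, c(20, 20, 5, 5)), 0)
})
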