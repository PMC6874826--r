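eval_fixture <- function() {
  ann <- read_annotations_coco(system.file("extdata",
    "synthetic_coco_annotations.json", package = "standcount"))
  dets <- read_detections_coco(system.file("extdata",
    "synthetic_coco_detections.json", package = "standcount"),
    categories = ann$categories)
  list(gts = ann$gts, dets = dets)
}

one_box_df <- function(image_id, b, class = "seedling", conf = NULL) {
  d <- data.frame(image_id = image_id, x_min = b[1], y_min = b[2],
                  x_max = b[3], y_max = b[4], class = class)
  if (!is.null(conf)) d$conf <- conf
  d
}

test_that("matching follows the greedy confidence-ordered rule", {
  gt <- one_box_df(1, c(0, 0, 100, 100))
  # IOU 0.6: offset so inter/union = 0.6 -> use 0..100 vs 0..100 shifted y by 25
  det <- one_box_df(1, c(0, 25, 100, 125), conf = 0.9)
  expect_gt(iou(box(0, 0, 100, 100), box(0, 25, 100, 125)), 0.5)
  m <- match_at_iou(gt, det, 0.5)
  expect_true(m$det$tp)
  expect_equal(m$fn, 0L)
  m2 <- match_at_iou(gt, det, 0.7)
  expect_false(m2$det$tp)
  expect_equal(m2$fn, 1L)
  # two detections on one GT: the higher-confidence one wins
  det2 <- rbind(one_box_df(1, c(0, 5, 100, 105), conf = 0.7),
                one_box_df(1, c(0, 2, 100, 102), conf = 0.95))
  m3 <- match_at_iou(gt, det2, 0.5)
  expect_equal(m3$det$tp[order(-m3$det$conf)], c(TRUE, FALSE))
  expect_equal(m3$fn, 0L)
})

test_that("average precision reproduces the 101-point worked example", {
  # 2 GT; a TP at conf 0.9 then a FP at conf 0.8:
  # precision 1 holds up to recall 0.5 -> AP = 51/101
  expect_equal(average_precision(c(TRUE, FALSE), c(0.9, 0.8), 2), 51 / 101)
  expect_equal(average_precision(c(TRUE, TRUE), c(0.9, 0.8), 2), 1)
  expect_equal(average_precision(c(FALSE, FALSE), c(0.9, 0.8), 2), 0)
  expect_true(is.na(average_precision(logical(0), numeric(0), 0)))
})

test_that("AR100 averages recall across the requested IOU thresholds", {
  gt <- one_box_df(1, c(0, 0, 100, 100))
  # overlap passes at 0.5 only (IOU ~ 0.538)
  det <- one_box_df(1, c(0, 30, 100, 130), conf = 0.9)
  o <- iou(box(0, 0, 100, 100), box(0, 30, 100, 130))
  expect_gt(o, 0.5); expect_lt(o, 0.55)
  expect_equal(average_recall_100(gt, det, seq(0.5, 0.95, 0.05)), 1 / 10)
  expect_equal(average_recall_100(gt, det, 0.5), 1)
  expect_equal(average_recall_100(gt, det[0, ], 0.5), 0)
})

test_that("AP and AR are non-increasing in the IOU threshold", {
  fx <- eval_fixture()
  g <- fx$gts[fx$gts$class == "seedling", ]
  d <- fx$dets[fx$dets$class == "seedling", ]
  aps <- vapply(seq(0.5, 0.95, 0.05), function(t) {
    m <- match_at_iou(g, d, t)
    average_precision(m$det$tp, m$det$conf, m$n_gt)
  }, numeric(1))
  ars <- vapply(seq(0.5, 0.95, 0.05), function(t)
    average_recall_100(g, d, t), numeric(1))
  expect_true(all(diff(aps) <= 1e-12))
  expect_true(all(diff(ars) <= 1e-12))
})

test_that("a perfect detector scores 1 on every metric", {
  set.seed(41)
  gts <- do.call(rbind, lapply(1:3, function(img) {
    b <- random_box_matrix(3, max_xy = 800)
    data.frame(image_id = img, x_min = b[, 1], y_min = b[, 2],
               x_max = b[, 3], y_max = b[, 4], class = "seedling")
  }))
  dets <- gts
  dets$conf <- runif(nrow(dets), 0.6, 1)
  s <- evaluate_detections(gts, dets)
  expect_equal(s$overall$mAP, c(1, 1))
  expect_equal(s$overall$mAR100, c(1, 1))
  expect_equal(s$overall$F1, c(1, 1))
  expect_equal(s$per_category$F1_50, 1)
})

test_that("summary metrics match the frozen COCO-protocol reference values", {
  # expected values computed once by an independent implementation of the
  # COCO protocol (greedy score-ordered matching, 101-point interpolation,
  # maxDets = 100) run on the same fixture files
  fx <- eval_fixture()
  s <- evaluate_detections(fx$gts, fx$dets)
  per <- s$per_category
  expect_equal(per$AP_50[per$class == "seedling"], 0.7897602260226022,
               tolerance = 1e-4)
  expect_equal(per$AP_all[per$class == "seedling"], 0.30009734902061636,
               tolerance = 1e-4)
  expect_equal(per$AR100_50[per$class == "seedling"], 0.8181818181818182,
               tolerance = 1e-4)
  expect_equal(per$AP_50[per$class == "weed"], 1.0, tolerance = 1e-4)
  expect_equal(s$overall$mAP, c(0.8948801130113011, 0.338827552398097),
               tolerance = 1e-4)
  expect_equal(s$overall$mAR100, c(0.9090909090909092, 0.4075757575757576),
               tolerance = 1e-4)
})

test_that("F1 is consistent with the reported mAP and mAR100", {
  fx <- eval_fixture()
  s <- evaluate_detections(fx$gts, fx$dets)
  expect_equal(s$overall$F1,
               2 * s$overall$mAP * s$overall$mAR100 /
                 (s$overall$mAP + s$overall$mAR100))
  expect_true(all(s$overall$mAP[2] <= s$overall$mAP[1]))
})

test_that("categories without ground truth are NA and excluded from means", {
  fx <- eval_fixture()
  s <- evaluate_detections(fx$gts, fx$dets,
                           categories = c("seedling", "weed", "other"))
  expect_true(is.na(s$per_category$AP_50[s$per_category$class == "other"]))
  s2 <- evaluate_detections(fx$gts, fx$dets)
  expect_equal(s$overall$mAP, s2$overall$mAP)
  expect_error(evaluate_detections(fx$gts[0, ], fx$dets), "empty ground truth")
})

test_that("metrics and PR curves are written to disk", {
  fx <- eval_fixture()
  s <- evaluate_detections(fx$gts, fx$dets)
  js <- tempfile(fileext = ".json"); prd <- tempfile()
  write_metrics(s, js, prd)
  back <- jsonlite::fromJSON(js)
  expect_equal(back$overall$mAP, s$overall$mAP, tolerance = 1e-12)
  pr <- read.csv(file.path(prd, "pr_seedling.csv"))
  expect_equal(nrow(pr), 101L)
  expect_true(all(diff(pr$precision) <= 1e-12)) # monotone envelope
})
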