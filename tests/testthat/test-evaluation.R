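test_that("IoU matches area arithmetic and is symmetric", {
  a <- boxes_df(0, 0, 10, 10)
  expect_equal(box_iou(a, a)[1, 1], 1)
  b <- boxes_df(5, 5, 15, 15)
  expect_equal(box_iou(a, b)[1, 1], 25 / 175)
  expect_equal(box_iou(b, a)[1, 1], box_iou(a, b)[1, 1])
  far <- boxes_df(100, 100, 110, 110)
  expect_equal(box_iou(a, far)[1, 1], 0)

  set.seed(3)
  x <- runif(6, 0, 50); y <- runif(6, 0, 50)
  r1 <- boxes_df(x[1:3], y[1:3], x[1:3] + 20, y[1:3] + 15)
  r2 <- boxes_df(x[4:6], y[4:6], x[4:6] + 25, y[4:6] + 10)
  expect_equal(box_iou(r1, r2), t(box_iou(r2, r1)))
  expect_true(all(box_iou(r1, r2) >= 0 & box_iou(r1, r2) <= 1))
})

test_that("greedy matching counts TP/FP/FN correctly on simple layouts", {
  gt <- boxes_df(c(0, 50), c(0, 0), c(20, 70), c(20, 20))
  pred <- gt; pred$score <- c(0.9, 0.8)
  m <- match_detections(pred, gt, 0.5)
  expect_equal(m$true_positives, 2L)
  expect_equal(m$false_positives, 0L)
  expect_equal(m$false_negatives, 0L)

  m0 <- match_detections(empty_boxes(), gt, 0.5)
  expect_equal(m0$false_negatives, 2L)
  expect_equal(m0$true_positives, 0L)

  m1 <- match_detections(pred, empty_boxes(), 0.5)
  expect_equal(m1$false_positives, 2L)
})

test_that("greedy matching agrees with brute-force enumeration on random instances", {
  for (s in 1:200) {
    inst <- random_match_instance(s)
    for (thr in c(0.3, 0.5)) {
      m <- match_detections(inst$pred, inst$gt, thr)
      expect_equal(m$true_positives, bf_max_matches(inst$pred, inst$gt, thr),
                   info = sprintf("seed %d thr %.1f", s, thr))
      expect_equal(m$false_positives, nrow(inst$pred) - m$true_positives)
      expect_equal(m$false_negatives, nrow(inst$gt) - m$true_positives)
    }
  }
})

test_that("average precision reproduces hand-computed PR areas", {
  gt <- boxes_df(10, 10, 30, 30)
  perfect <- gt; perfect$score <- 0.9
  expect_equal(average_precision(perfect, gt, 0.5), 1)

  # an FP outscoring the only TP: PR points (0,0) then (1, 0.5) -> AP 0.5
  pred <- rbind(boxes_df(100, 100, 120, 120, score = 0.95),
                boxes_df(10, 10, 30, 30, score = 0.9))
  expect_equal(average_precision(pred, gt, 0.5), 0.5)

  expect_equal(average_precision(empty_boxes(), gt, 0.5), 0)
  expect_true(is.na(average_precision(perfect, empty_boxes(), 0.5)))
})

test_that("average precision agrees with a numeric-integration oracle", {
  for (s in 201:260) {
    inst <- random_match_instance(s)
    if (!nrow(inst$pred)) next
    ap <- average_precision(inst$pred, inst$gt, 0.3)
    expect_equal(ap, ap_numeric_oracle(inst$pred, inst$gt, 0.3),
                 tolerance = 1e-3, info = sprintf("seed %d", s))
  }
})

test_that("AP is invariant to monotone score transforms and penalises FPs", {
  inst <- random_match_instance(42)
  pred <- inst$pred
  ap0 <- average_precision(pred, inst$gt, 0.3)
  squashed <- pred; squashed$score <- plogis(5 * pred$score)
  expect_equal(average_precision(squashed, inst$gt, 0.3), ap0)

  low_fp <- rbind(pred, boxes_df(400, 400, 430, 430,
                                 score = min(pred$score) / 2))
  expect_lte(average_precision(low_fp, inst$gt, 0.3), ap0 + 1e-12)
  expect_true(ap0 >= 0 && ap0 <= 1)
})

test_that("mAP pools over images and is non-increasing in the IoU threshold", {
  p <- small_scene_params()
  preds <- list(); gts <- list()
  for (s in 1:20) {
    p$seed <- s
    sc <- generate_scene(p, id = sprintf("s%d", s))
    gts[[sc$id]] <- boxes_for(sc$ground_truth, sc$id)
    preds[[sc$id]] <- oracle_detect(sc, oracle_noise(jitter_px_sd = 6,
                                                     miss_rate = 0.1,
                                                     false_positive_rate = 1,
                                                     seed = s))
  }
  maps <- mean_ap(preds, gts, thresholds = c(0.3, 0.5))
  expect_gte(maps[[1]], maps[[2]])
  expect_true(all(maps >= 0 & maps <= 1))

  rep <- evaluate_detections(preds, gts)
  expect_equal(rep$summary$ap, unname(maps))
  expect_equal(rep$summary$tp + rep$summary$fn,
               rep(sum(vapply(gts, nrow, numeric(1))), 2))
})

test_that("101-point interpolation stays close to all-points AP", {
  inst <- random_match_instance(77)
  a <- average_precision(inst$pred, inst$gt, 0.3, "all")
  b <- average_precision(inst$pred, inst$gt, 0.3, "points101")
  expect_lt(abs(a - b), 0.05)
})

test_that("count error rate reproduces the percent-error arithmetic", {
  expect_equal(count_error_rate(16.8, 16.2), 100 * 0.6 / 16.2)
  expect_equal(round(count_error_rate(16.8, 16.2), 2), 3.7)
  expect_equal(count_error_rate(20, 16), 25)
  expect_equal(count_error_rate(16.2, 16.2), 0)
  expect_error(count_error_rate(10, 0))
})
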