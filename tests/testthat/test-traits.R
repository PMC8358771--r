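test_that("stomatal density divides the full count by the field area", {
  cal <- calibration()
  b <- boxes_df(seq(0, 950, by = 50), 100, seq(30, 980, by = 50), 140)[1:20, ]
  expect_equal(stomatal_density(b, cal), 20 / 0.984)
  expect_equal(stomatal_density(empty_boxes(), cal), 0)
  # scores and marginal status do not change SD
  b$score <- runif(20)
  expect_equal(stomatal_density(b, cal), 20 / 0.984)
})

test_that("marginal boxes are those touching the image limits", {
  cal <- calibration()   # 1024 x 768
  expect_true(is_marginal(boxes_df(0, 100, 60, 140), cal))
  expect_true(is_marginal(boxes_df(900, 100, 1024, 140), cal))
  expect_true(is_marginal(boxes_df(100, 0.2, 160, 40), cal))
  expect_true(is_marginal(boxes_df(100, 700, 160, 767.8), cal))
  expect_false(is_marginal(boxes_df(100, 100, 200, 150), cal))
  expect_equal(is_marginal(empty_boxes(), cal), logical())
})

test_that("stomatal size converts box extents to micrometres", {
  sz <- stomatal_size(boxes_df(0, 0, 78, 49), calibration())
  expect_equal(sz$length_um, 78 * 1.116)   # 87.05
  expect_equal(sz$width_um, 49 * 1.116)    # 54.68
  one <- stomatal_size(boxes_df(10, 10, 11, 11), calibration())
  expect_equal(one$length_um, 1.116)

  cal10 <- calibration("10x", um_per_px = 0.445)
  small <- stomatal_size(boxes_df(0, 0, 63, 39), cal10)
  expect_equal(small$length_um, 63 * 0.445)  # ~28 um regime
})

test_that("per-image records exclude marginal stomata from size statistics only", {
  cal <- calibration()
  det <- rbind(boxes_df(0, 100, 60, 140),        # marginal (xmin = 0)
               boxes_df(980, 100, 1024, 140),    # marginal (xmax = W)
               boxes_df(100, 100, 178, 149),
               boxes_df(300, 300, 380, 350),
               boxes_df(500, 500, 576, 548))
  rec <- measure_image(det, cal)
  expect_equal(rec$stomata_count, 5L)
  expect_equal(rec$sd_per_mm2, 5 / 0.984)
  expect_equal(nrow(rec$measurements), 3L)
  expect_equal(rec$mean_length_um, mean(c(78, 80, 76)) * 1.116)

  all_marg <- rbind(boxes_df(0, 100, 60, 140), boxes_df(0, 300, 50, 340))
  rec2 <- measure_image(all_marg, cal)
  expect_gt(rec2$sd_per_mm2, 0)
  expect_false(rec2$ss_defined)
  expect_true(is.na(rec2$mean_length_um))

  # adding marginal boxes leaves the size statistics untouched
  more <- rbind(det, boxes_df(0, 500, 40, 540))
  rec3 <- measure_image(more, cal)
  expect_equal(rec3$mean_length_um, rec$mean_length_um)
  expect_equal(rec3$stomata_count, 6L)
})

test_that("pixel-to-micrometre conversion commutes with averaging", {
  set.seed(5)
  x <- runif(30, 0, 900); y <- runif(30, 60, 700)
  det <- boxes_df(x, y, x + runif(30, 60, 90), y + runif(30, 40, 55))
  cal <- calibration()
  rec <- measure_image(det, cal)
  keep <- !is_marginal(det, cal)
  expect_equal(rec$mean_length_um,
               cal$um_per_px * mean((det$xmax - det$xmin)[keep]))
})

test_that("gap clustering recovers stomatal files and interval lengths", {
  cal <- calibration()
  yc <- c(98, 100, 102, 300, 305, 500)
  det <- boxes_df(seq(100, 600, by = 100), yc - 20,
                  seq(170, 670, by = 100), yc + 20)
  fp <- stomatal_files(det, cal, gap_factor = 1.5)
  expect_equal(fp$file_y_px, c(100, 302.5, 500))
  expect_equal(fp$intervals_um, c(202.5, 197.5) * 1.116)
  expect_equal(round(fp$intervals_um, 1), c(226.0, 220.4))
  expect_length(fp$members, 3L)
  expect_equal(sort(fp$members[[1]]), 1:3)

  single <- stomatal_files(boxes_df(10, 10, 80, 50), cal)
  expect_length(single$file_y_px, 1L)
  expect_length(single$intervals_um, 0L)

  none <- stomatal_files(empty_boxes(), cal)
  expect_length(none$file_y_px, 0L)
})

test_that("zero-noise oracle detections reproduce scene-true traits exactly", {
  p <- small_scene_params(seed = 31, allow_marginal = FALSE,
                          stoma_y_jitter_um = 0)
  sc <- generate_scene(p)
  det <- oracle_detect(sc, oracle_noise())
  cal <- p$calibration
  rec <- measure_image(det, cal)
  expect_equal(rec$sd_per_mm2, nrow(sc$stomata) / cal$field_area_mm2)
  expect_equal(rec$mean_length_um, mean(sc$stomata$length_um))
  expect_equal(rec$mean_width_um, mean(sc$stomata$width_um))
})

test_that("trait tables cover every image and flag marginal stomata", {
  p <- small_scene_params()
  images <- list(); boxes <- list()
  for (s in 1:5) {
    p$seed <- s
    sc <- generate_scene(p, id = sprintf("im%d", s))
    images[[s]] <- sc$ground_truth$images
    boxes[[s]] <- sc$ground_truth$boxes
  }
  set <- annotation_set(do.call(rbind, images), do.call(rbind, boxes))
  cal <- small_cal()
  tabs <- measure_set(set, cal)
  expect_equal(nrow(tabs$traits), 5L)
  expect_equal(sum(tabs$traits$count), nrow(set$boxes))
  expect_equal(nrow(tabs$measurements), nrow(set$boxes))
  expect_true(is.logical(tabs$measurements$marginal))
})
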