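# Shared fixtures and independent oracles for the test suite.

# Small calibration for fast scenes: 512 x 384 px at 1.116 um/px, with the
# field area derived from the pixel geometry so density expectations are
# exact on the small field.
small_cal <- function() {
  cal <- calibration(image_width_px = 512L, image_height_px = 384L)
  cal$field_area_mm2 <- field_area_from_pixels(cal)
  cal
}

small_scene_params <- function(seed = 1L, ...) {
  args <- list(...)
  defaults <- list(image_width_px = 512L, image_height_px = 384L,
                   calibration = small_cal(), density_per_mm2 = 25,
                   file_interval_um = 150, seed = seed)
  do.call(scene_params, utils::modifyList(defaults, args))
}

# Non-adversarial random matching instance: ground-truth boxes far enough
# apart that any box can overlap at most one of them, so greedy matching is
# provably optimal and must agree with the brute-force oracle.
random_match_instance <- function(seed) {
  set.seed(seed)
  ng <- sample.int(5L, 1L)
  centers <- matrix(numeric(), 0, 2)
  while (nrow(centers) < ng) {
    cand <- runif(2, 60, 440)
    if (!nrow(centers) ||
        all(sqrt(colSums((t(centers) - cand)^2)) > 120)) {
      centers <- rbind(centers, cand)
    }
  }
  w <- runif(ng, 30, 50); h <- runif(ng, 30, 50)
  gt <- boxes_df(centers[, 1] - w / 2, centers[, 2] - h / 2,
                 centers[, 1] + w / 2, centers[, 2] + h / 2)
  # predictions: jittered copies of a random subset plus far-away FPs
  take <- which(runif(ng) < 0.8)
  pred <- gt[take, , drop = FALSE]
  if (nrow(pred)) {
    for (col in c("xmin", "ymin", "xmax", "ymax"))
      pred[[col]] <- pmax(pred[[col]] + rnorm(nrow(pred), 0, 4), 0)
    swap <- pred$xmin >= pred$xmax | pred$ymin >= pred$ymax
    pred <- pred[!swap, , drop = FALSE]
  }
  n_fp <- sample.int(3L, 1L) - 1L
  if (n_fp > 0) {
    fx <- runif(n_fp, 500, 600); fy <- runif(n_fp, 500, 600)
    pred <- rbind(pred, boxes_df(fx, fy, fx + 40, fy + 40))
  }
  if (nrow(pred)) pred$score <- runif(nrow(pred))
  list(pred = pred, gt = gt)
}

# Brute-force maximum one-to-one matching: enumerates all assignments of
# predictions to ground-truth boxes with IoU >= threshold and returns the
# maximum number of matched pairs.
bf_max_matches <- function(pred, gt, iou_threshold) {
  if (!nrow(pred) || !nrow(gt)) return(0L)
  feas <- box_iou(pred, gt) >= iou_threshold
  best <- 0L
  recurse <- function(p, free_gt, count) {
    if (p > nrow(pred)) { best <<- max(best, count); return(invisible()) }
    recurse(p + 1L, free_gt, count)  # leave prediction p unmatched
    for (g in which(free_gt)) {
      if (feas[p, g]) {
        free_gt2 <- free_gt; free_gt2[g] <- FALSE
        recurse(p + 1L, free_gt2, count + 1L)
      }
    }
  }
  recurse(1L, rep(TRUE, nrow(gt)), 0L)
  best
}

# Independent numeric AP oracle: rebuilds the PR curve from score-ordered
# greedy matching and integrates the precision envelope on a fine recall
# grid rather than summing exact rectangles.
ap_numeric_oracle <- function(pred, gt, iou_threshold, grid_n = 20000L) {
  n_gt <- nrow(gt)
  if (n_gt == 0L) return(NA_real_)
  if (!nrow(pred)) return(0)
  ord <- order(-pred$score)
  taken <- logical(n_gt)
  tp <- logical(length(ord))
  for (k in seq_along(ord)) {
    iou <- box_iou(pred[ord[k], , drop = FALSE], gt)[1, ]
    iou[taken] <- -1
    g <- which.max(iou)
    if (iou[g] >= iou_threshold && iou[g] > 0) {
      taken[g] <- TRUE; tp[k] <- TRUE
    }
  }
  cum_tp <- cumsum(tp)
  prec <- cum_tp / seq_along(cum_tp)
  rec <- cum_tp / n_gt
  grid <- (seq_len(grid_n) - 0.5) / grid_n
  p_at <- Reduce(pmax, lapply(seq_along(rec), function(i)
    ifelse(rec[i] >= grid, prec[i], 0)), accumulate = FALSE,
    init = numeric(grid_n))
  mean(p_at)
}
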