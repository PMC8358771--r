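#' Detector configuration
#'
#' Shared post-processing settings for all detector implementations: minimum
#' score, non-maximum-suppression IoU threshold, and the detection cap.
#'
#' @param score_threshold minimum detection score in `[0, 1]`.
#' @param nms_iou_threshold NMS overlap threshold in `[0, 1]`.
#' @param max_detections maximum detections returned per image (>= 1).
#' @return An object of class `"detector_config"`.
#' @export
detector_config <- function(score_threshold = 0.5, nms_iou_threshold = 0.5,
                            max_detections = 300L) {
  stopifnot(score_threshold >= 0, score_threshold <= 1,
            nms_iou_threshold >= 0, nms_iou_threshold <= 1,
            max_detections >= 1)
  structure(list(score_threshold = score_threshold,
                 nms_iou_threshold = nms_iou_threshold,
                 max_detections = as.integer(max_detections)),
            class = "detector_config")
}

#' Oracle detector noise model
#'
#' Corruption applied by [oracle_detect()] to ground truth: each true box is
#' independently missed with probability `miss_rate`, surviving boxes get
#' Gaussian coordinate jitter, and `Poisson(false_positive_rate)` spurious
#' boxes are added per image.
#'
#' @param jitter_px_sd coordinate jitter sd in pixels (>= 0).
#' @param miss_rate per-box miss probability in `[0, 1)`.
#' @param false_positive_rate expected spurious boxes per image (>= 0).
#' @param seed integer seed.
#' @return An object of class `"oracle_noise"`.
#' @export
oracle_noise <- function(jitter_px_sd = 0, miss_rate = 0,
                         false_positive_rate = 0, seed = 1L) {
  stopifnot(jitter_px_sd >= 0, miss_rate >= 0, miss_rate < 1,
            false_positive_rate >= 0)
  structure(list(jitter_px_sd = jitter_px_sd, miss_rate = miss_rate,
                 false_positive_rate = false_positive_rate,
                 seed = as.integer(seed)),
            class = "oracle_noise")
}

#' Oracle detector driven by synthetic ground truth
#'
#' A detector stand-in for testing the downstream pipeline: it reads the
#' scene's ground truth and corrupts it according to an [oracle_noise()]
#' model. With zero noise the returned box set equals the ground truth.
#' True boxes get scores uniform on `[score_threshold, 1]`; false positives
#' uniform on `[score_threshold, 0.7]`, so score-ranked evaluation orders
#' them meaningfully. Deterministic given scene and seed.
#'
#' @param scene a [generate_scene()] result.
#' @param noise an [oracle_noise()].
#' @param config a [detector_config()].
#' @return A box data.frame sorted by descending score.
#' @export
oracle_detect <- function(scene, noise = oracle_noise(),
                          config = detector_config()) {
  stopifnot(inherits(scene, "synthetic_scene"), inherits(noise, "oracle_noise"))
  set.seed(noise$seed)
  W <- scene$params$image_width_px; H <- scene$params$image_height_px
  gt <- boxes_for(scene$ground_truth, scene$id)
  keep <- if (nrow(gt)) runif(nrow(gt)) >= noise$miss_rate else logical()
  out <- gt[keep, , drop = FALSE]
  if (nrow(out) && noise$jitter_px_sd > 0) {
    for (col in c("xmin", "ymin", "xmax", "ymax"))
      out[[col]] <- out[[col]] + rnorm(nrow(out), 0, noise$jitter_px_sd)
    xlo <- pmin(out$xmin, out$xmax); xhi <- pmax(out$xmin, out$xmax)
    ylo <- pmin(out$ymin, out$ymax); yhi <- pmax(out$ymin, out$ymax)
    out$xmin <- pmax(xlo, 0); out$xmax <- pmin(pmax(xhi, xlo + 1), W)
    out$ymin <- pmax(ylo, 0); out$ymax <- pmin(pmax(yhi, ylo + 1), H)
    out <- clip_boxes(out, W, H)
  }
  if (nrow(out))
    out$score <- runif(nrow(out), config$score_threshold, 1)
  n_fp <- if (noise$false_positive_rate > 0)
    rpois(1L, noise$false_positive_rate) else 0L
  if (n_fp > 0L) {
    st <- scene$stomata
    L <- if (nrow(st)) mean(st$length_px) else W / 12
    Wd <- if (nrow(st)) mean(st$width_px) else H / 15
    cx <- runif(n_fp, 0, W); cy <- runif(n_fp, 0, H)
    fp <- data.frame(xmin = cx - L / 2, ymin = cy - Wd / 2,
                     xmax = cx + L / 2, ymax = cy + Wd / 2,
                     score = runif(n_fp, config$score_threshold, 0.7),
                     label = "stoma", stringsAsFactors = FALSE)
    fp <- clip_boxes(fp, W, H)
    out <- rbind(out, fp)
  }
  out <- out[order(-out$score, box_area(out), out$xmin), , drop = FALSE]
  out <- head(out, config$max_detections)
  rownames(out) <- NULL
  out
}

#' Non-maximum suppression
#'
#' Greedy suppression in descending score order: a box is removed if its IoU
#' with an already-kept box exceeds `iou_threshold`. Ties in score are
#' broken by smaller area, then lower `xmin`, making the result
#' deterministic; the output is always a subset of the input and the
#' operation is idempotent.
#'
#' @param boxes a scored box data.frame.
#' @param iou_threshold overlap threshold in `[0, 1]`.
#' @return The retained boxes, sorted by descending score.
#' @export
nms <- function(boxes, iou_threshold = 0.5) {
  if (nrow(boxes) <= 1L) return(boxes)
  sc <- ifelse(is.na(boxes$score), 1, boxes$score)
  ord <- order(-sc, box_area(boxes), boxes$xmin)
  b <- boxes[ord, , drop = FALSE]
  iou <- box_iou(b, b)
  keep <- logical(nrow(b))
  for (i in seq_len(nrow(b))) {
    keep[i] <- !any(keep & iou[i, ] > iou_threshold)
  }
  out <- b[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Template-matching baseline detector
#'
#' A classical, non-neural detector so the pipeline runs end to end without
#' trained weights: the image is matched by normalized cross-correlation
#' against rendered dumbbell templates over a small grid of stomata sizes;
#' local correlation maxima above the score threshold become boxes of the
#' matched template size, followed by non-maximum suppression. It is a
#' pipeline stand-in, not an accuracy baseline comparable to a trained
#' neural detector.
#'
#' @param image an [image_record()] with pixels.
#' @param template_sizes data.frame with columns `length_px`, `width_px`;
#'   defaults to the wheat regime implied by the image's calibration
#'   (87.2 x 54.4 um).
#' @param config a [detector_config()]; scores are NCC values, so a
#'   `score_threshold` around 0.5 is a reasonable default.
#' @param render a [render_params()] defining the template appearance.
#' @return A box data.frame sorted by descending score (empty for blank
#'   images).
#' @export
baseline_detect <- function(image, template_sizes = NULL,
                            config = detector_config(),
                            render = render_params()) {
  stopifnot(inherits(image, "image_record"), !is.null(image$pixels))
  if (is.null(template_sizes)) {
    upp <- if (!is.null(image$calibration)) image$calibration$um_per_px else 1.116
    template_sizes <- data.frame(length_px = 87.2 / upp * c(0.8, 1, 1.2),
                                 width_px = 54.4 / upp * c(0.8, 1, 1.2))
  }
  I <- image$pixels
  cand <- empty_boxes()
  for (k in seq_len(nrow(template_sizes))) {
    L <- template_sizes$length_px[k]; Wd <- template_sizes$width_px[k]
    tmpl <- dumbbell_template(L, Wd, noise = render)
    if (nrow(tmpl) >= nrow(I) || ncol(tmpl) >= ncol(I))
      stop("template larger than image")
    ncc <- ncc_map(I, tmpl)
    pk <- local_maxima(ncc, config$score_threshold)
    if (nrow(pk)) {
      b <- data.frame(xmin = pk$x - L / 2, ymin = pk$y - Wd / 2,
                      xmax = pk$x + L / 2, ymax = pk$y + Wd / 2,
                      score = pmin(pk$value, 1), label = "stoma",
                      stringsAsFactors = FALSE)
      b <- clip_boxes(b, image$width_px, image$height_px)
      cand <- rbind(cand, b)
    }
  }
  out <- nms(cand, config$nms_iou_threshold)
  out <- head(out, config$max_detections)
  rownames(out) <- NULL
  out
}

# Normalized cross-correlation of image I with template (both matrices
# [y, x]); returns a matrix of I's size with values in [-1, 1].
ncc_map <- function(I, tmpl) {
  t0 <- tmpl - mean(tmpl)
  denom_t <- sqrt(sum(t0^2))
  if (denom_t == 0) return(matrix(0, nrow(I), ncol(I)))
  n <- length(tmpl)
  ones <- matrix(1, nrow(tmpl), ncol(tmpl))
  ei <- as_ebimage(I)
  cross <- from_ebimage(EBImage::filter2(ei, t(t0), boundary = "replicate"))
  s1 <- from_ebimage(EBImage::filter2(ei, t(ones), boundary = "replicate"))
  s2 <- from_ebimage(EBImage::filter2(as_ebimage(I^2), t(ones),
                                      boundary = "replicate"))
  local_sd <- sqrt(pmax(s2 - s1^2 / n, 0))
  out <- cross / (local_sd * denom_t)
  out[local_sd < 1e-8] <- 0
  pmin(pmax(out, -1), 1)
}

# Strict local maxima of `m` above `threshold` over the 8-neighbourhood.
# Returns a data.frame with pixel-centre coordinates (x, y) and values.
local_maxima <- function(m, threshold) {
  H <- nrow(m); W <- ncol(m)
  if (H < 3 || W < 3) return(data.frame(x = numeric(), y = numeric(),
                                        value = numeric()))
  core <- m[2:(H - 1), 2:(W - 1), drop = FALSE]
  is_max <- core > threshold
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- m[2:(H - 1) + di, 2:(W - 1) + dj, drop = FALSE]
    is_max <- is_max & core >= nb
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(x = numeric(), y = numeric(),
                                    value = numeric()))
  data.frame(x = idx[, 2] + 1 - 0.5, y = idx[, 1] + 1 - 0.5,
             value = core[idx])
}
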