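#' Pipeline configuration
#'
#' Flat configuration for the batch pipeline, loadable from a YAML file of
#' top-level keys. Recognised keys (all optional) are the arguments of this
#' constructor; calibration fields are nested under `calibration:`.
#'
#' @param calibration a [calibration()].
#' @param detector `"oracle"` or `"baseline"`.
#' @param score_threshold,nms_iou_threshold,max_detections see
#'   [detector_config()].
#' @param jitter_px_sd,miss_rate,false_positive_rate oracle noise (see
#'   [oracle_noise()]); used when `detector = "oracle"`.
#' @param resize_factor,padded_width_px,padded_height_px,tile_width_px,tile_height_px,min_box_retention
#'   see [tiling_spec()].
#' @param eval_thresholds IoU thresholds for evaluation.
#' @param seed integer seed for all pipeline randomness.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(calibration = stomabox::calibration(),
                            detector = c("oracle", "baseline"),
                            score_threshold = 0.5, nms_iou_threshold = 0.5,
                            max_detections = 300L,
                            jitter_px_sd = 0, miss_rate = 0,
                            false_positive_rate = 0,
                            resize_factor = 0.5,
                            padded_width_px = 2048L, padded_height_px = 1024L,
                            tile_width_px = 1024L, tile_height_px = 1024L,
                            min_box_retention = 0.5,
                            eval_thresholds = c(0.3, 0.5),
                            seed = 1L) {
  detector <- match.arg(detector)
  structure(list(calibration = calibration, detector = detector,
                 detector_config = detector_config(score_threshold,
                                                   nms_iou_threshold,
                                                   max_detections),
                 oracle_noise = oracle_noise(jitter_px_sd, miss_rate,
                                             false_positive_rate,
                                             seed = seed),
                 tiling = tiling_spec(resize_factor, padded_width_px,
                                      padded_height_px, tile_width_px,
                                      tile_height_px, min_box_retention),
                 eval_thresholds = eval_thresholds,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of flat keys matching [pipeline_config()]
#'   arguments, with calibration fields nested under `calibration:`.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  cal_args <- y$calibration
  y$calibration <- NULL
  cal <- if (is.null(cal_args)) calibration() else
    do.call(calibration, cal_args)
  known <- intersect(names(y), names(formals(pipeline_config)))
  do.call(pipeline_config, c(list(calibration = cal), y[known]))
}

log_step <- function(...) message(sprintf("[stomabox %s] ",
                                          format(Sys.time(), "%H:%M:%S")),
                                  sprintf(...))

#' Simulate a batch of synthetic imprint images with ground truth
#'
#' Generates `n_images` scenes (seeds `seed`, `seed + 1`, ...), renders each
#' to a PNG under `out_dir/images/`, and writes the pooled ground truth as
#' COCO JSON plus the scene parameters as YAML.
#'
#' @param n_images number of images.
#' @param out_dir output directory (created if needed).
#' @param params a [scene_params()] template; its seed is replaced per image.
#' @param render a [render_params()].
#' @param seed base seed.
#' @return Invisibly, a list with the ground-truth [annotation_set()], the
#'   list of scenes, and output paths.
#' @export
run_simulate <- function(n_images, out_dir, params = scene_params(),
                         render = render_params(), seed = 1L) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  scenes <- list(); images <- list(); boxes <- list()
  for (i in seq_len(n_images)) {
    p <- params; p$seed <- as.integer(seed + i - 1L)
    id <- sprintf("sim_%04d", i)
    sc <- generate_scene(p, id = id)
    rp <- render; rp$seed <- p$seed
    img <- render_image(sc, rp)
    write_image(img, file.path(out_dir, "images", paste0(id, ".png")))
    scenes[[id]] <- sc
    images[[i]] <- sc$ground_truth$images
    if (nrow(sc$ground_truth$boxes)) boxes[[length(boxes) + 1L]] <-
      sc$ground_truth$boxes
  }
  gt <- annotation_set(do.call(rbind, images),
                       if (length(boxes)) do.call(rbind, boxes) else
                         cbind(image_id = character(), empty_boxes()))
  gt_path <- file.path(out_dir, "ground_truth.json")
  write_coco(gt, gt_path)
  cfg <- params[setdiff(names(params), "calibration")]
  cfg$calibration <- params$calibration[names(params$calibration)]
  yaml::write_yaml(cfg, file.path(out_dir, "scene_params.yaml"))
  log_step("simulate: %d images -> %s", n_images, out_dir)
  invisible(list(ground_truth = gt, scenes = scenes, dir = out_dir,
                 gt_path = gt_path))
}

#' Prepare detector training tiles from an annotation export
#'
#' Reads COCO or Labelbox-style annotations, applies the resize / pad /
#' split chain, and writes the tiled dataset as COCO JSON.
#'
#' @param in_path annotation file.
#' @param out_path output COCO JSON path.
#' @param spec a [tiling_spec()].
#' @param format `"coco"` or `"labelbox"`.
#' @param image_dir optional directory of source images (PNG/TIFF named by
#'   image id); when given, tile images are written next to `out_path`.
#' @return Invisibly, the tiled [annotation_set()].
#' @export
run_prepare <- function(in_path, out_path, spec = tiling_spec(),
                        format = c("coco", "labelbox"), image_dir = NULL) {
  format <- match.arg(format)
  set <- if (format == "coco") read_coco(in_path) else read_labelbox(in_path)
  images <- NULL
  if (!is.null(image_dir)) {
    images <- list()
    for (id in set$images$id) {
      for (ext in c(".png", ".tif", ".tiff")) {
        f <- file.path(image_dir, paste0(id, ext))
        if (file.exists(f)) { images[[id]] <- read_image(f, id = id); break }
      }
    }
  }
  res <- prepare_training_tiles(set, spec, images = images)
  write_coco(res$set, out_path)
  if (!is.null(res$images)) {
    tdir <- file.path(dirname(out_path), "tiles")
    dir.create(tdir, showWarnings = FALSE, recursive = TRUE)
    for (img in res$images)
      write_image(img, file.path(tdir, paste0(img$id, ".png")))
  }
  log_step("prepare: %d images -> %d tiles (%s)", nrow(set$images),
           nrow(res$set$images), out_path)
  invisible(res$set)
}

#' Run a detector over a directory of images
#'
#' Applies [baseline_detect()] to every PNG/TIFF in `image_dir` and writes
#' scored detections in COCO results format. (The oracle detector operates
#' on scenes, not images; use [oracle_detect()] directly or [run_demo()].)
#'
#' @param image_dir directory of images.
#' @param out_path output COCO results JSON.
#' @param config a [detector_config()].
#' @param calibration a [calibration()] used for default template sizes.
#' @return Invisibly, the predictions as an [annotation_set()].
#' @export
run_detect <- function(image_dir, out_path, config = detector_config(),
                       calibration = stomabox::calibration()) {
  files <- list.files(image_dir, pattern = "\\.(png|tif|tiff)$",
                      full.names = TRUE)
  if (!length(files)) stop("no images found in ", image_dir)
  images <- list(); boxes <- list()
  for (f in files) {
    img <- read_image(f, calibration = calibration)
    det <- baseline_detect(img, config = config)
    images[[length(images) + 1L]] <-
      data.frame(id = img$id, width_px = img$width_px,
                 height_px = img$height_px, stringsAsFactors = FALSE)
    if (nrow(det)) boxes[[length(boxes) + 1L]] <- cbind(image_id = img$id, det)
  }
  preds <- annotation_set(do.call(rbind, images),
                          if (length(boxes)) do.call(rbind, boxes) else
                            cbind(image_id = character(), empty_boxes()))
  write_coco_results(preds, out_path)
  log_step("detect: %d images, %d detections -> %s", length(files),
           nrow(preds$boxes), out_path)
  invisible(preds)
}

#' Evaluate detections against ground truth
#'
#' @param results_path COCO results JSON of predictions.
#' @param gt_path COCO ground-truth JSON.
#' @param out_path optional CSV path for the summary table.
#' @param thresholds IoU thresholds.
#' @return The [evaluate_detections()] report, invisibly if `out_path` is
#'   written.
#' @export
run_evaluate <- function(results_path, gt_path, out_path = NULL,
                         thresholds = c(0.3, 0.5)) {
  gt <- read_coco(gt_path)
  preds <- load_predictions(results_path, gt)
  rep <- evaluate_detections(boxes_by_image(preds), boxes_by_image(gt),
                             thresholds)
  if (!is.null(out_path)) {
    write.csv(rep$summary, out_path, row.names = FALSE)
    log_step("evaluate: mAP %s -> %s",
             paste(sprintf("%.3f", rep$summary$ap), collapse = "/"), out_path)
    return(invisible(rep))
  }
  rep
}

#' Compute trait tables from detections
#'
#' @param results_path COCO results JSON (or ground-truth JSON) of boxes.
#' @param gt_path COCO JSON supplying the image registry (defaults to
#'   `results_path` when that file is a full COCO dataset).
#' @param calibration a [calibration()].
#' @param out_prefix path prefix; writes `<prefix>_traits.csv` and
#'   `<prefix>_measurements.csv`.
#' @return Invisibly, the [measure_set()] tables.
#' @export
run_traits <- function(results_path, gt_path = NULL,
                       calibration = stomabox::calibration(),
                       out_prefix = NULL) {
  set <- if (is.null(gt_path)) read_coco(results_path) else
    load_predictions(results_path, read_coco(gt_path))
  tabs <- measure_set(set, calibration)
  if (!is.null(out_prefix)) {
    write.csv(tabs$traits, paste0(out_prefix, "_traits.csv"),
              row.names = FALSE)
    write.csv(tabs$measurements, paste0(out_prefix, "_measurements.csv"),
              row.names = FALSE)
    log_step("traits: %d images, %d stomata -> %s_*.csv",
             nrow(tabs$traits), nrow(tabs$measurements), out_prefix)
  }
  invisible(tabs)
}

#' Statistical analyses on trait tables
#'
#' Runs Welch's t test and the subsampling power simulation on the per-image
#' densities of two trait tables, and the Pearson test on the
#' density-length relation of their union.
#'
#' @param traits_a,traits_b per-image trait data.frames (from
#'   [run_traits()] / [measure_set()]) for the two groups.
#' @param sample_sizes subsample sizes for the power simulation.
#' @param reps repetitions per power simulation.
#' @param alpha significance level.
#' @param seed integer seed.
#' @return A list with `welch` (htest), `power` (named list of
#'   [power_simulation()] results) and `pearson` (htest on pooled
#'   `sd_per_mm2` vs `mean_length_um`, `NULL` if sizes are undefined).
#' @export
run_stats <- function(traits_a, traits_b, sample_sizes = c(4L, 10L),
                      reps = 10000L, alpha = 0.05, seed = 1L) {
  a <- traits_a$sd_per_mm2; b <- traits_b$sd_per_mm2
  power <- lapply(sample_sizes, function(n)
    power_simulation(a, b, sample_size = n, reps = reps, alpha = alpha,
                     seed = seed + n))
  names(power) <- paste0("n", sample_sizes)
  pooled <- rbind(traits_a, traits_b)
  pooled <- pooled[pooled$ss_defined, , drop = FALSE]
  pear <- if (nrow(pooled) >= 3 && sd(pooled$sd_per_mm2) > 0 &&
                sd(pooled$mean_length_um) > 0)
    pearson_test(pooled$sd_per_mm2, pooled$mean_length_um) else NULL
  list(welch = welch_t(a, b), power = power, pearson = pear)
}

#' End-to-end demonstration on synthetic data
#'
#' Generates scenes for two density groups, detects stomata with the noisy
#' oracle, evaluates against ground truth, extracts traits and runs the
#' statistics — the full batch pipeline on synthetic data, without writing
#' any file.
#'
#' @param n_per_group images per density group.
#' @param density_a,density_b group densities (stomata/mm^2).
#' @param noise an [oracle_noise()] model for the detector.
#' @param params a [scene_params()] template.
#' @param seed base seed.
#' @param reps power-simulation repetitions.
#' @return A list with `evaluation` (a [evaluate_detections()] report
#'   pooled over all images), `traits` (named per-group trait tables) and
#'   `stats` (the [run_stats()] output).
#' @export
run_demo <- function(n_per_group = 25L, density_a = 23.2, density_b = 16.8,
                     noise = oracle_noise(jitter_px_sd = 2, miss_rate = 0.03,
                                          false_positive_rate = 0.5),
                     params = scene_params(), seed = 1L, reps = 2000L) {
  make_group <- function(density, offset) {
    scenes <- lapply(seq_len(n_per_group), function(i) {
      p <- params
      p$density_per_mm2 <- density
      p$seed <- as.integer(seed + offset + i)
      generate_scene(p, id = sprintf("g%d_%03d", offset, i))
    })
    preds <- lapply(scenes, function(sc) {
      nz <- noise; nz$seed <- sc$params$seed + 77777L
      oracle_detect(sc, nz)
    })
    names(preds) <- vapply(scenes, `[[`, "", "id")
    gts <- lapply(scenes, function(sc) boxes_for(sc$ground_truth, sc$id))
    names(gts) <- names(preds)
    list(scenes = scenes, preds = preds, gts = gts)
  }
  ga <- make_group(density_a, 0L)
  gb <- make_group(density_b, 100000L)
  preds <- c(ga$preds, gb$preds); gts <- c(ga$gts, gb$gts)
  ev <- evaluate_detections(preds, gts, thresholds = c(0.3, 0.5))
  traits_of <- function(g) {
    do.call(rbind, lapply(names(g$preds), function(id) {
      rec <- measure_image(g$preds[[id]], params$calibration, image_id = id)
      data.frame(image_id = id, count = rec$stomata_count,
                 sd_per_mm2 = rec$sd_per_mm2,
                 mean_length_um = rec$mean_length_um,
                 mean_width_um = rec$mean_width_um,
                 ss_defined = rec$ss_defined, stringsAsFactors = FALSE)
    }))
  }
  ta <- traits_of(ga); tb <- traits_of(gb)
  st <- run_stats(ta, tb, reps = reps, seed = seed)
  list(evaluation = ev, traits = list(a = ta, b = tb), stats = st)
}
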