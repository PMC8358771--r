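#' Stomatal density from detections
#'
#' Count of all detected stomata divided by the microscopic field area.
#' Marginal (border-touching) boxes are included in the count: a stoma
#' straddling the frame is still a stoma on the leaf.
#'
#' @param detections box data.frame.
#' @param calibration a [calibration()].
#' @return Density in stomata per mm^2.
#' @examples
#' stomatal_density(boxes_df(10, 10, 80, 60), calibration())  # 1 / 0.984
#' @export
stomatal_density <- function(detections, calibration) {
  stopifnot(inherits(calibration, "calibration"))
  nrow(detections) / calibration$field_area_mm2
}

#' Is a box marginal (touching the image border)?
#'
#' A box is marginal when any coordinate sits at the lower limit (0) or the
#' upper limit (the image width for x, height for y), within a tolerance
#' `eps` that accommodates real-valued detector output (the rule is stated
#' on integer limits).
#'
#' @param boxes box data.frame.
#' @param calibration a [calibration()] supplying the image dimensions.
#' @param eps border tolerance in pixels.
#' @return Logical vector, one element per box.
#' @export
is_marginal <- function(boxes, calibration, eps = 0.5) {
  stopifnot(inherits(calibration, "calibration"))
  W <- calibration$image_width_px; H <- calibration$image_height_px
  if (!nrow(boxes)) return(logical())
  boxes$xmin <= eps | boxes$ymin <= eps |
    boxes$xmax >= W - eps | boxes$ymax >= H - eps
}

#' Stomatal length and width from a bounding box
#'
#' The box x-extent is the stomatal length (guard-cell long axis) and the
#' y-extent the stomatal width, scaled from pixels to micrometres. Assumes
#' the acquisition protocol aligns cell files with the image x-axis.
#'
#' @param boxes box data.frame with non-degenerate boxes.
#' @param calibration a [calibration()].
#' @return data.frame with columns `length_um`, `width_um`.
#' @examples
#' stomatal_size(boxes_df(0, 0, 78, 49), calibration())  # 87.05 x 54.68 um
#' @export
stomatal_size <- function(boxes, calibration) {
  stopifnot(inherits(calibration, "calibration"))
  validate_boxes(boxes)
  data.frame(length_um = (boxes$xmax - boxes$xmin) * calibration$um_per_px,
             width_um = (boxes$ymax - boxes$ymin) * calibration$um_per_px)
}

#' Per-image trait record: density and size statistics
#'
#' Stomatal density is computed over all detections; size statistics are
#' computed over non-marginal detections only, since a border-clipped box
#' underestimates its stoma. When every detection is marginal the means are
#' `NA` and flagged via `ss_defined = FALSE`.
#'
#' @param detections box data.frame.
#' @param calibration a [calibration()].
#' @param image_id identifier stored in the record.
#' @param eps border tolerance passed to [is_marginal()].
#' @return A list of class `"trait_record"`: `image_id`, `stomata_count`,
#'   `sd_per_mm2`, `measurements` (data.frame of non-marginal stomata with
#'   `length_um`, `width_um`, `marginal`), `mean_length_um`,
#'   `mean_width_um`, `ss_defined`.
#' @export
measure_image <- function(detections, calibration, image_id = "image",
                          eps = 0.5) {
  stopifnot(inherits(calibration, "calibration"))
  marg <- is_marginal(detections, calibration, eps)
  sizes <- if (nrow(detections)) stomatal_size(detections, calibration) else
    data.frame(length_um = numeric(), width_um = numeric())
  meas <- cbind(detections, sizes, marginal = marg)
  keep <- meas[!marg, , drop = FALSE]
  ss_defined <- nrow(keep) > 0L
  structure(list(image_id = image_id,
                 stomata_count = nrow(detections),
                 sd_per_mm2 = stomatal_density(detections, calibration),
                 measurements = keep,
                 mean_length_um = if (ss_defined) mean(keep$length_um) else NA_real_,
                 mean_width_um = if (ss_defined) mean(keep$width_um) else NA_real_,
                 ss_defined = ss_defined),
            class = "trait_record")
}

#' @export
print.trait_record <- function(x, ...) {
  cat(sprintf("trait_record '%s': %d stomata, SD %.2f /mm^2, SS %s\n",
              x$image_id, x$stomata_count, x$sd_per_mm2,
              if (x$ss_defined)
                sprintf("%.1f x %.1f um (n=%d non-marginal)",
                        x$mean_length_um, x$mean_width_um,
                        nrow(x$measurements))
              else "undefined (all marginal)"))
  invisible(x)
}

#' Trait tables for a whole annotation set
#'
#' Applies [measure_image()] to every image and assembles the per-image
#' trait table and the per-stoma measurement table, the two CSV outputs of
#' the phenotyping pipeline.
#'
#' @param set an [annotation_set()] of detections.
#' @param calibration a [calibration()].
#' @param eps border tolerance passed to [is_marginal()].
#' @return `list(traits =, measurements =)`: per-image rows
#'   (`image_id, count, sd_per_mm2, mean_length_um, mean_width_um,
#'   ss_defined`) and per-stoma rows (`image_id, stoma_idx, length_um,
#'   width_um, marginal`). The measurement table includes marginal stomata,
#'   flagged, so downstream filtering stays explicit.
#' @export
measure_set <- function(set, calibration, eps = 0.5) {
  stopifnot(inherits(set, "annotation_set"))
  traits <- list(); meas <- list()
  for (id in set$images$id) {
    det <- boxes_for(set, id)
    rec <- measure_image(det, calibration, image_id = id, eps = eps)
    traits[[length(traits) + 1L]] <-
      data.frame(image_id = id, count = rec$stomata_count,
                 sd_per_mm2 = rec$sd_per_mm2,
                 mean_length_um = rec$mean_length_um,
                 mean_width_um = rec$mean_width_um,
                 ss_defined = rec$ss_defined, stringsAsFactors = FALSE)
    if (nrow(det)) {
      sz <- stomatal_size(det, calibration)
      meas[[length(meas) + 1L]] <-
        data.frame(image_id = id, stoma_idx = seq_len(nrow(det)),
                   length_um = sz$length_um, width_um = sz$width_um,
                   marginal = is_marginal(det, calibration, eps),
                   stringsAsFactors = FALSE)
    }
  }
  list(traits = do.call(rbind, traits),
       measurements = if (length(meas)) do.call(rbind, meas) else
         data.frame(image_id = character(), stoma_idx = integer(),
                    length_um = numeric(), width_um = numeric(),
                    marginal = logical()))
}

#' Stomatal-file pattern and interval lengths
#'
#' Groups detections into horizontal stomatal files by 1-D gap clustering of
#' their y-centres: sorted centres start a new file wherever the gap to the
#' previous centre exceeds `gap_factor` times the median box height. The
#' file position is the mean y-centre of its members; intervals are the
#' consecutive differences between file positions, converted to
#' micrometres.
#'
#' @param detections box data.frame with at least one row (an empty input
#'   yields an empty pattern).
#' @param calibration a [calibration()].
#' @param gap_factor multiple of the median box height that opens a new
#'   file.
#' @return A list of class `"file_pattern"`: `file_y_px` (sorted file
#'   positions), `intervals_um` (length = files - 1) and `members` (list of
#'   detection row indices per file).
#' @examples
#' b <- boxes_df(rep(100, 3), c(90, 92, 94), rep(170, 3), c(110, 112, 114))
#' stomatal_files(b, calibration())
#' @export
stomatal_files <- function(detections, calibration, gap_factor = 1.5) {
  stopifnot(inherits(calibration, "calibration"), gap_factor > 0)
  if (!nrow(detections)) {
    return(structure(list(file_y_px = numeric(), intervals_um = numeric(),
                          members = list()), class = "file_pattern"))
  }
  yc <- (detections$ymin + detections$ymax) / 2
  h <- median(detections$ymax - detections$ymin)
  ord <- order(yc)
  gaps <- diff(yc[ord])
  file_of_sorted <- cumsum(c(1L, as.integer(gaps > gap_factor * h)))
  members <- split(ord, file_of_sorted)
  file_y <- vapply(members, function(i) mean(yc[i]), numeric(1))
  o <- order(file_y)
  file_y <- unname(file_y[o]); members <- members[o]
  names(members) <- NULL
  structure(list(file_y_px = unname(file_y),
                 intervals_um = diff(file_y) * calibration$um_per_px,
                 members = members),
            class = "file_pattern")
}

#' Modes of a stomatal-file interval distribution
#'
#' Kernel-density mode extraction for pooled file-interval lengths: the
#' `n_modes` highest local maxima of the default Gaussian kernel density
#' estimate. Used to summarise interval distributions that mix two spacing
#' regimes (e.g. alternating narrow/wide file spacings on an abaxial
#' surface).
#'
#' @param intervals_um numeric vector of interval lengths (um).
#' @param n_modes number of modes to report.
#' @return Sorted numeric vector of mode positions (um), length up to
#'   `n_modes`.
#' @export
interval_modes <- function(intervals_um, n_modes = 2L) {
  stopifnot(length(intervals_um) >= 2, n_modes >= 1)
  d <- stats::density(intervals_um)
  i <- seq(2, length(d$y) - 1)
  peaks <- i[d$y[i] > d$y[i - 1] & d$y[i] >= d$y[i + 1]]
  if (!length(peaks)) peaks <- which.max(d$y)
  top <- peaks[order(-d$y[peaks])][seq_len(min(n_modes, length(peaks)))]
  sort(d$x[top])
}

#' @export
print.file_pattern <- function(x, ...) {
  cat(sprintf("file_pattern: %d file(s)", length(x$file_y_px)))
  if (length(x$intervals_um))
    cat(sprintf(", intervals %s um",
                paste(sprintf("%.1f", x$intervals_um), collapse = ", ")))
  cat("\n")
  invisible(x)
}
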