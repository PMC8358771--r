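#' Parameters for a synthetic leaf-imprint scene
#'
#' Describes a wheat-like imprint micrograph: dumbbell-shaped stomata
#' arranged in horizontal files, with stomatal density, size distribution and
#' file spacing set to the regimes typical of Triticeae leaf surfaces.
#' Defaults emulate an abaxial bread-wheat surface: density 16.8 stomata/mm^2,
#' stomatal length 87.2 +/- 8 um, width 54.4 +/- 5 um, and files alternating
#' at 130 and 230 um spacing along the y-axis. The adaxial regime is reached
#' by `density_per_mm2 = 23.2`; the small-stomata regime of e.g.
#' *Brachypodium* by `length_um_mean = 27.9, length_um_sd = 3.5,
#' width_um_mean = 17.3, width_um_sd = 2.8` with a x10 calibration.
#'
#' @param image_width_px,image_height_px scene dimensions in pixels.
#' @param calibration a [calibration()]; sets the um/px scale and the field
#'   area used to convert `density_per_mm2` into an expected count.
#' @param density_per_mm2 target stomatal density (>= 0).
#' @param file_interval_um mean spacing between stomatal files along y (um);
#'   a vector is recycled, so `c(130, 230)` gives alternating intervals.
#' @param file_interval_jitter_um Gaussian jitter of each file position (um).
#' @param length_um_mean,length_um_sd stomatal length distribution
#'   (normal truncated > 0); length runs along x.
#' @param width_um_mean,width_um_sd stomatal width distribution (y extent).
#' @param stoma_y_jitter_um Gaussian scatter of stoma centres about their
#'   file (um).
#' @param sd_ss_coupling slope linking the scene's realised density
#'   deviation (stomata/mm^2) to its mean length deviation (um); 0 means
#'   size and density are independent.
#' @param allow_marginal if `TRUE`, `marginal_fraction` of stomata may
#'   straddle the left/right image border (their ground-truth boxes are
#'   clipped), exercising the marginal-exclusion rule of the traits layer.
#' @param marginal_fraction fraction of stomata placed across a border.
#' @param max_overlap_frac maximum tolerated overlap between two stomata,
#'   as a fraction of the smaller box's area (default 0: no overlap).
#' @param seed integer seed; scenes are bit-identical given identical
#'   parameters.
#' @return An object of class `"scene_params"`.
#' @export
scene_params <- function(image_width_px = 1024L, image_height_px = 768L,
                         calibration = stomabox::calibration(),
                         density_per_mm2 = 16.8,
                         file_interval_um = c(130, 230),
                         file_interval_jitter_um = 5,
                         length_um_mean = 87.2, length_um_sd = 8,
                         width_um_mean = 54.4, width_um_sd = 5,
                         stoma_y_jitter_um = 3,
                         sd_ss_coupling = 0,
                         allow_marginal = TRUE, marginal_fraction = 0.1,
                         max_overlap_frac = 0, seed = 1L) {
  stopifnot(inherits(calibration, "calibration"),
            density_per_mm2 >= 0,
            all(file_interval_um > 0), file_interval_jitter_um >= 0,
            length_um_mean > 0, length_um_sd >= 0,
            width_um_mean > 0, width_um_sd >= 0,
            stoma_y_jitter_um >= 0,
            marginal_fraction >= 0, marginal_fraction <= 1,
            max_overlap_frac >= 0, max_overlap_frac < 1)
  structure(list(image_width_px = as.integer(image_width_px),
                 image_height_px = as.integer(image_height_px),
                 calibration = calibration,
                 density_per_mm2 = density_per_mm2,
                 file_interval_um = file_interval_um,
                 file_interval_jitter_um = file_interval_jitter_um,
                 length_um_mean = length_um_mean, length_um_sd = length_um_sd,
                 width_um_mean = width_um_mean, width_um_sd = width_um_sd,
                 stoma_y_jitter_um = stoma_y_jitter_um,
                 sd_ss_coupling = sd_ss_coupling,
                 allow_marginal = isTRUE(allow_marginal),
                 marginal_fraction = marginal_fraction,
                 max_overlap_frac = max_overlap_frac,
                 seed = as.integer(seed)),
            class = "scene_params")
}

rnorm_trunc_pos <- function(n, mean, sd) {
  if (n == 0L) return(numeric())
  x <- rnorm(n, mean, sd)
  while (any(bad <- x <= 0)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Generate a synthetic stomatal scene
#'
#' Places stomata on horizontal files. The stomata count is drawn
#' Poisson with mean `density_per_mm2 x field_area_mm2`; lengths and widths
#' come from the configured truncated normals; positions are rejection
#' sampled so that no two boxes overlap beyond `max_overlap_frac` (stomata
#' never overlap in real epidermis). Ground-truth boxes are the circumscribed
#' boxes of the stomata, clipped to the image for border-straddling stomata.
#'
#' @param params a [scene_params()].
#' @param id image id for the ground-truth annotation set.
#' @return An object of class `"synthetic_scene"`: a list with `params`,
#'   `file_y_px`, a `stomata` data.frame (`center_x_px, center_y_px,
#'   length_px, width_px, length_um, width_um, file, marginal`) and
#'   `ground_truth`, an [annotation_set()].
#' @export
generate_scene <- function(params, id = "scene") {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  cal <- params$calibration
  upp <- cal$um_per_px
  W <- params$image_width_px; H <- params$image_height_px
  H_um <- H * upp

  # stomatal file positions along y, intervals recycled, per-file jitter
  intervals <- params$file_interval_um
  y <- runif(1, 0, min(intervals[1], H_um))
  file_y_um <- y
  k <- 1L
  repeat {
    y <- y + intervals[(k - 1L) %% length(intervals) + 1L]
    if (y >= H_um) break
    file_y_um <- c(file_y_um, y)
    k <- k + 1L
  }
  file_y_um <- file_y_um + rnorm(length(file_y_um), 0,
                                 params$file_interval_jitter_um)
  file_y_um <- sort(pmin(pmax(file_y_um, 0), H_um))
  file_y_px <- file_y_um / upp

  n <- if (params$density_per_mm2 == 0) 0L else
    rpois(1L, params$density_per_mm2 * cal$field_area_mm2)

  if (n > 0L && length(file_y_px) == 0L)
    stop("scene capacity error: no stomatal file fits the image height")

  mean_len <- params$length_um_mean
  if (params$sd_ss_coupling != 0) {
    realised_density <- n / cal$field_area_mm2
    mean_len <- mean_len + params$sd_ss_coupling *
      (realised_density - params$density_per_mm2)
    mean_len <- max(mean_len, 1e-6)
  }
  length_um <- rnorm_trunc_pos(n, mean_len, params$length_um_sd)
  width_um <- rnorm_trunc_pos(n, params$width_um_mean, params$width_um_sd)
  length_px <- length_um / upp
  width_px <- width_um / upp
  marginal <- if (params$allow_marginal && n > 0L)
    runif(n) < params$marginal_fraction else rep(FALSE, n)

  cx <- cy <- numeric(n); file_idx <- integer(n)
  placed <- 0L
  attempts <- 0L; max_attempts <- 100L * max(n, 1L)
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop(sprintf(paste0("scene capacity error: placed %d of %d stomata ",
                          "after %d attempts; density too high for ",
                          "non-overlapping placement"),
                   placed, n, attempts - 1L))
    i <- placed + 1L
    f <- sample.int(length(file_y_px), 1L)
    yy <- file_y_px[f] + rnorm(1, 0, params$stoma_y_jitter_um / upp)
    hl <- length_px[i] / 2
    if (marginal[i]) {
      side <- runif(1) < 0.5
      xx <- if (side) runif(1, -hl, hl) else runif(1, W - hl, W + hl)
    } else {
      if (W <= length_px[i]) next
      xx <- runif(1, hl, W - hl)
    }
    ok <- TRUE
    if (placed > 0L && params$max_overlap_frac < 1) {
      j <- seq_len(placed)
      ix <- pmax(0, pmin(xx + hl, cx[j] + length_px[j] / 2) -
                    pmax(xx - hl, cx[j] - length_px[j] / 2))
      iy <- pmax(0, pmin(yy + width_px[i] / 2, cy[j] + width_px[j] / 2) -
                    pmax(yy - width_px[i] / 2, cy[j] - width_px[j] / 2))
      smaller <- pmin(length_px[i] * width_px[i], length_px[j] * width_px[j])
      ok <- all(ix * iy <= params$max_overlap_frac * smaller)
    }
    if (ok) {
      placed <- i
      cx[i] <- xx; cy[i] <- yy; file_idx[i] <- f
    }
  }

  stomata <- data.frame(center_x_px = cx, center_y_px = cy,
                        length_px = length_px[seq_len(n)],
                        width_px = width_px[seq_len(n)],
                        length_um = length_um[seq_len(n)],
                        width_um = width_um[seq_len(n)],
                        file = file_idx, marginal = marginal[seq_len(n)])
  gt <- if (n == 0L) empty_boxes() else
    data.frame(xmin = stomata$center_x_px - stomata$length_px / 2,
                   ymin = stomata$center_y_px - stomata$width_px / 2,
                   xmax = stomata$center_x_px + stomata$length_px / 2,
                   ymax = stomata$center_y_px + stomata$width_px / 2,
                   score = NA_real_, label = "stoma",
                   stringsAsFactors = FALSE)
  gt <- clip_boxes(gt, W, H)
  validate_boxes(gt, where = id)
  images <- data.frame(id = id, width_px = W, height_px = H,
                       stringsAsFactors = FALSE)
  ground_truth <- annotation_set(images,
                                 if (nrow(gt)) cbind(image_id = id, gt) else
                                   cbind(image_id = character(), empty_boxes()))
  structure(list(params = params, id = id, file_y_px = file_y_px,
                 stomata = stomata, ground_truth = ground_truth),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene '%s': %d stomata on %d file(s), %d x %d px\n",
              x$id, nrow(x$stomata), length(x$file_y_px),
              x$params$image_width_px, x$params$image_height_px))
  invisible(x)
}

#' Generate per-image stomata counts for two density groups
#'
#' Draws per-image counts from a negative binomial with mean
#' `density x field_area_mm2` and dispersion `size = dispersion`
#' (`dispersion = Inf` gives the Poisson limit). Emulates the per-image
#' count tables behind density comparisons of two leaf surfaces.
#'
#' @param density_a,density_b group densities (stomata/mm^2, >= 0).
#' @param n_images images per group (>= 1).
#' @param dispersion negative-binomial size parameter (> 0, may be `Inf`).
#' @param calibration a [calibration()] supplying the field area.
#' @param seed integer seed.
#' @return `list(a =, b =)` of integer count vectors of length `n_images`.
#' @export
generate_count_dataset <- function(density_a, density_b, n_images,
                                   dispersion = Inf,
                                   calibration = stomabox::calibration(),
                                   seed = 1L) {
  stopifnot(density_a >= 0, density_b >= 0, n_images >= 1,
            is.numeric(dispersion), dispersion > 0)
  set.seed(seed)
  area <- calibration$field_area_mm2
  draw <- function(mu) {
    if (mu == 0) return(integer(n_images))
    if (is.infinite(dispersion)) rpois(n_images, mu) else
      rnbinom(n_images, size = dispersion, mu = mu)
  }
  list(a = draw(density_a * area), b = draw(density_b * area))
}

#' Generate correlated (density, mean length) field pairs
#'
#' Bivariate-normal pairs emulating per-field stomatal density against the
#' field's mean stomatal length, with a target Pearson correlation `rho`.
#'
#' @param n_fields number of microscopic fields (>= 2).
#' @param sd_mean,sd_sd marginal distribution of density (stomata/mm^2).
#' @param len_mean,len_sd marginal distribution of mean length (um).
#' @param rho target correlation in `[-1, 1]`.
#' @param seed integer seed.
#' @return data.frame with columns `sd_per_mm2` and `mean_length_um`.
#' @export
generate_correlated_traits <- function(n_fields, sd_mean = 20, sd_sd = 3,
                                       len_mean = 87, len_sd = 4,
                                       rho = -0.6, seed = 1L) {
  stopifnot(n_fields >= 2, rho >= -1, rho <= 1, sd_sd > 0, len_sd > 0)
  set.seed(seed)
  z1 <- rnorm(n_fields); z2 <- rnorm(n_fields)
  data.frame(sd_per_mm2 = sd_mean + sd_sd * z1,
             mean_length_um = len_mean +
               len_sd * (rho * z1 + sqrt(1 - rho^2) * z2))
}
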