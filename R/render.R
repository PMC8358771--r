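#' Rendering parameters for synthetic micrographs
#'
#' Controls the appearance and noise of rendered imprint images. Intensities
#' are on `[0, 1]` with a light background and darker stomata, as in
#' bright-field imprint micrographs. Noise is off by default.
#'
#' @param background background intensity.
#' @param lobe_intensity intensity of the two guard-cell lobes.
#' @param pore_intensity intensity of the central pore (darkest).
#' @param blur_sigma_px Gaussian blur sigma in pixels (0 = off).
#' @param noise_sd additive Gaussian noise sd (0 = off).
#' @param dust_rate expected number of dark dust specks per image (Poisson).
#' @param seed integer seed for the noise draws.
#' @return An object of class `"render_params"`.
#' @export
render_params <- function(background = 0.85, lobe_intensity = 0.45,
                          pore_intensity = 0.12, blur_sigma_px = 0,
                          noise_sd = 0, dust_rate = 0, seed = 1L) {
  stopifnot(blur_sigma_px >= 0, noise_sd >= 0, dust_rate >= 0)
  structure(list(background = background, lobe_intensity = lobe_intensity,
                 pore_intensity = pore_intensity,
                 blur_sigma_px = blur_sigma_px, noise_sd = noise_sd,
                 dust_rate = dust_rate, seed = as.integer(seed)),
            class = "render_params")
}

# Paint one dumbbell-shaped stoma into `px` (matrix [y, x]): two filled
# ellipse lobes flanking a darker pore rectangle, long axis horizontal.
# Pixel (i, j) has centre (x = j - 0.5, y = i - 0.5). The painted extent
# exactly fills the circumscribed box [cx +/- L/2] x [cy +/- W/2].
draw_dumbbell <- function(px, cx, cy, L, W, lobe, pore) {
  H <- nrow(px); Wim <- ncol(px)
  j0 <- max(1L, floor(cx - L / 2 + 0.5)); j1 <- min(Wim, ceiling(cx + L / 2 + 0.5))
  i0 <- max(1L, floor(cy - W / 2 + 0.5)); i1 <- min(H, ceiling(cy + W / 2 + 0.5))
  if (j0 > j1 || i0 > i1) return(px)
  xs <- (j0:j1) - 0.5; ys <- (i0:i1) - 0.5
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  a <- 0.2 * L; b <- 0.5 * W
  in_lobe <- (((X - (cx - 0.3 * L)) / a)^2 + ((Y - cy) / b)^2 <= 1) |
    (((X - (cx + 0.3 * L)) / a)^2 + ((Y - cy) / b)^2 <= 1)
  in_pore <- abs(X - cx) <= 0.15 * L & abs(Y - cy) <= 0.18 * W
  blk <- px[i0:i1, j0:j1, drop = FALSE]
  blk[in_lobe] <- lobe
  blk[in_pore] <- pore
  px[i0:i1, j0:j1] <- blk
  px
}

#' Render a synthetic scene into a grayscale micrograph
#'
#' Each stoma is drawn as a dumbbell (two elongated guard-cell lobes
#' flanking a darker central pore) inside its ground-truth box, on a light
#' background, followed by optional Gaussian blur, additive noise and dark
#' dust specks. Rendering is bit-identical given the same scene and
#' rendering seed.
#'
#' @param scene a [generate_scene()] result.
#' @param noise a [render_params()].
#' @return An [image_record()] of the scene's dimensions.
#' @export
render_image <- function(scene, noise = render_params()) {
  stopifnot(inherits(scene, "synthetic_scene"),
            inherits(noise, "render_params"))
  p <- scene$params
  px <- matrix(noise$background, nrow = p$image_height_px,
               ncol = p$image_width_px)
  st <- scene$stomata
  for (i in seq_len(nrow(st))) {
    px <- draw_dumbbell(px, st$center_x_px[i], st$center_y_px[i],
                        st$length_px[i], st$width_px[i],
                        noise$lobe_intensity, noise$pore_intensity)
  }
  set.seed(noise$seed)
  if (noise$blur_sigma_px > 0)
    px <- from_ebimage(EBImage::gblur(as_ebimage(px),
                                      sigma = noise$blur_sigma_px))
  if (noise$dust_rate > 0) {
    nd <- rpois(1L, noise$dust_rate)
    for (k in seq_len(nd)) {
      dx <- runif(1, 0, p$image_width_px); dy <- runif(1, 0, p$image_height_px)
      r <- runif(1, 1, 3)
      i0 <- max(1L, floor(dy - r)); i1 <- min(p$image_height_px, ceiling(dy + r))
      j0 <- max(1L, floor(dx - r)); j1 <- min(p$image_width_px, ceiling(dx + r))
      if (i0 > i1 || j0 > j1) next
      X <- matrix((j0:j1) - 0.5, i1 - i0 + 1L, j1 - j0 + 1L, byrow = TRUE)
      Y <- matrix((i0:i1) - 0.5, i1 - i0 + 1L, j1 - j0 + 1L)
      blk <- px[i0:i1, j0:j1, drop = FALSE]
      blk[(X - dx)^2 + (Y - dy)^2 <= r^2] <- noise$pore_intensity
      px[i0:i1, j0:j1] <- blk
    }
  }
  if (noise$noise_sd > 0)
    px <- px + matrix(rnorm(length(px), 0, noise$noise_sd), nrow(px), ncol(px))
  px <- pmin(pmax(px, 0), 1)
  image_record(px, id = scene$id, calibration = p$calibration)
}

#' Render a dumbbell template for matched filtering
#'
#' A single stoma rendered on a small canvas with odd dimensions, for use as
#' a normalized cross-correlation kernel in [baseline_detect()].
#'
#' @param length_px,width_px stoma dimensions in pixels.
#' @param margin_px background margin around the stoma.
#' @param noise a [render_params()] supplying the intensity scheme.
#' @return A numeric matrix `[height, width]` with odd dimensions; the
#'   stoma size is stored in attributes `length_px` and `width_px`.
#' @export
dumbbell_template <- function(length_px, width_px, margin_px = 2,
                              noise = render_params()) {
  stopifnot(length_px >= 3, width_px >= 3)
  w <- 2L * floor((length_px + 2 * margin_px) / 2) + 1L
  h <- 2L * floor((width_px + 2 * margin_px) / 2) + 1L
  px <- matrix(noise$background, nrow = h, ncol = w)
  px <- draw_dumbbell(px, w / 2, h / 2, length_px, width_px,
                      noise$lobe_intensity, noise$pore_intensity)
  attr(px, "length_px") <- length_px
  attr(px, "width_px") <- width_px
  px
}
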