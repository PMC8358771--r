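#' Microscope calibration
#'
#' Bundles the objective's pixel scale and the microscopic field geometry so
#' pixel measurements can be converted to micrometres and counts to densities
#' per mm^2. Defaults correspond to a x4 objective imaging a 1024 x 768 px
#' field of 0.984 mm^2 at 1.116 um/pixel; a x10 objective at 0.445 um/pixel
#' is the usual alternative for small-stomata species.
#'
#' `field_area_mm2` is an explicit constant rather than derived from
#' `um_per_px` and the image dimensions: published scale and area values are
#' typically rounded independently and need not be mutually consistent at
#' full precision (here 1024 x 768 x 1.116^2 = 0.979 mm^2, not 0.984).
#' Use [field_area_from_pixels()] when a derived area is wanted.
#'
#' @param objective label for the objective lens, e.g. `"4x"`.
#' @param um_per_px micrometres per pixel (> 0).
#' @param image_width_px,image_height_px field dimensions in pixels.
#' @param field_area_mm2 microscopic field area in mm^2 (> 0).
#' @return An object of class `"calibration"`.
#' @examples
#' cal <- calibration()
#' cal$um_per_px
#' field_area_from_pixels(cal)
#' @export
calibration <- function(objective = "4x", um_per_px = 1.116,
                        image_width_px = 1024L, image_height_px = 768L,
                        field_area_mm2 = 0.984) {
  stopifnot(is.numeric(um_per_px), length(um_per_px) == 1L, um_per_px > 0,
            is.numeric(field_area_mm2), field_area_mm2 > 0,
            image_width_px >= 1, image_height_px >= 1)
  structure(list(objective = objective,
                 um_per_px = um_per_px,
                 image_width_px = as.integer(image_width_px),
                 image_height_px = as.integer(image_height_px),
                 field_area_mm2 = field_area_mm2),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("calibration [%s]: %.4g um/px, %d x %d px, field %.4g mm^2\n",
              x$objective, x$um_per_px, x$image_width_px, x$image_height_px,
              x$field_area_mm2))
  invisible(x)
}

#' Field area derived from pixel geometry
#'
#' Secondary to the explicit `field_area_mm2` constant: the area implied by
#' the pixel scale and image dimensions.
#'
#' @param cal a [calibration()].
#' @return Area in mm^2.
#' @export
field_area_from_pixels <- function(cal) {
  stopifnot(inherits(cal, "calibration"))
  cal$image_width_px * cal$image_height_px * (cal$um_per_px / 1000)^2
}
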