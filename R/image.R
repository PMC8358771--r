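#' Image record
#'
#' A grayscale micrograph as a numeric matrix indexed `[row = y, col = x]`
#' with intensities in `[0, 1]`, plus its identifier and optional
#' calibration. `pixels` may be `NULL` for annotation-only workflows where
#' just the geometry matters (e.g. box remapping for a dataset whose images
#' are elsewhere).
#'
#' @param pixels numeric matrix `[height, width]`, or `NULL`.
#' @param id image identifier string.
#' @param width_px,height_px dimensions; inferred from `pixels` when given.
#' @param calibration optional [calibration()].
#' @return An object of class `"image_record"`.
#' @export
image_record <- function(pixels, id = "image", width_px = NULL,
                         height_px = NULL, calibration = NULL) {
  if (!is.null(pixels)) {
    stopifnot(is.matrix(pixels))
    width_px <- ncol(pixels); height_px <- nrow(pixels)
  }
  stopifnot(!is.null(width_px), !is.null(height_px),
            width_px >= 1, height_px >= 1)
  structure(list(id = as.character(id), pixels = pixels,
                 width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 calibration = calibration),
            class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("image_record '%s': %d x %d px%s\n", x$id, x$width_px,
              x$height_px, if (is.null(x$pixels)) " (no pixels)" else ""))
  invisible(x)
}

#' Read a PNG or TIFF micrograph
#'
#' Multi-channel images are averaged to grayscale.
#'
#' @param path image path; format chosen by extension (`.png`, `.tif(f)`).
#' @param id image identifier; defaults to the file name without extension.
#' @param calibration optional [calibration()] attached to the record.
#' @return An [image_record()].
#' @export
read_image <- function(path, id = NULL, calibration = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
               png = png::readPNG(path),
               tif = ,
               tiff = tiff::readTIFF(path),
               stop("unsupported image format: .", ext))
  if (length(dim(px)) == 3L) px <- apply(px, c(1, 2), mean)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  image_record(px, id = id, calibration = calibration)
}

#' Write an image record as PNG or TIFF
#'
#' @param image an [image_record()] with pixels.
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "image_record"), !is.null(image$pixels))
  px <- pmin(pmax(image$pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(px, path),
         tif = ,
         tiff = tiff::writeTIFF(px, path),
         stop("unsupported image format: .", ext))
  invisible(path)
}

# EBImage stores images [x, y]; the package stores [row = y, col = x].
as_ebimage <- function(pixels) EBImage::Image(t(pixels))
from_ebimage <- function(img) t(EBImage::imageData(img))
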