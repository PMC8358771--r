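#' Tiling specification for detector training images
#'
#' Describes the geometric preprocessing chain applied to annotated
#' micrographs before detector training: scale by `resize_factor`, pad with
#' black pixels on the right and bottom to `padded_width_px x
#' padded_height_px`, then cut into non-overlapping
#' `tile_width_px x tile_height_px` tiles. The defaults take a
#' 3072 x 2048 px (width x height) micrograph to two 1024 x 1024 tiles.
#'
#' Boxes clipped at a tile seam are kept in every tile where at least
#' `min_box_retention` of their area survives; smaller slivers are dropped.
#'
#' @param resize_factor linear scale factor (> 0).
#' @param padded_width_px,padded_height_px padded canvas size.
#' @param tile_width_px,tile_height_px tile size; must divide the padded size.
#' @param min_box_retention minimum retained area fraction in `(0, 1]`.
#' @return An object of class `"tiling_spec"`.
#' @export
tiling_spec <- function(resize_factor = 0.5,
                        padded_width_px = 2048L, padded_height_px = 1024L,
                        tile_width_px = 1024L, tile_height_px = 1024L,
                        min_box_retention = 0.5) {
  stopifnot(resize_factor > 0,
            padded_width_px %% tile_width_px == 0,
            padded_height_px %% tile_height_px == 0,
            min_box_retention > 0, min_box_retention <= 1)
  structure(list(resize_factor = resize_factor,
                 padded_width_px = as.integer(padded_width_px),
                 padded_height_px = as.integer(padded_height_px),
                 tile_width_px = as.integer(tile_width_px),
                 tile_height_px = as.integer(tile_height_px),
                 min_box_retention = min_box_retention),
            class = "tiling_spec")
}

#' Resize an image together with its boxes
#'
#' Pixel dimensions are scaled by `factor` (rounded to the nearest integer,
#' bilinear interpolation); every box coordinate is multiplied by `factor`,
#' so relative box positions are preserved exactly.
#'
#' @param image an [image_record()] (pixels optional).
#' @param boxes box data.frame in the image's coordinates.
#' @param factor linear scale factor (> 0).
#' @return `list(image =, boxes =)` in the new coordinate system.
#' @export
resize_with_boxes <- function(image, boxes, factor) {
  stopifnot(inherits(image, "image_record"), factor > 0)
  new_w <- as.integer(round(image$width_px * factor))
  new_h <- as.integer(round(image$height_px * factor))
  if (new_w < 1L || new_h < 1L) stop("resize factor collapses image to zero size")
  px <- image$pixels
  if (!is.null(px) && (new_w != image$width_px || new_h != image$height_px)) {
    px <- from_ebimage(EBImage::resize(as_ebimage(px), w = new_w, h = new_h))
  }
  b <- boxes
  if (nrow(b)) {
    b$xmin <- b$xmin * factor; b$xmax <- b$xmax * factor
    b$ymin <- b$ymin * factor; b$ymax <- b$ymax * factor
  }
  list(image = image_record(px, id = image$id, width_px = new_w,
                            height_px = new_h,
                            calibration = image$calibration),
       boxes = b)
}

#' Pad an image on the right and bottom
#'
#' Padding is appended on the right and bottom only, so the origin stays
#' fixed and box coordinates need no shift.
#'
#' @param image an [image_record()] (pixels optional).
#' @param boxes box data.frame; returned unchanged.
#' @param target_width_px,target_height_px target size, at least the current
#'   size.
#' @param fill padding intensity (default 0, black).
#' @return `list(image =, boxes =)`.
#' @export
pad_to <- function(image, boxes, target_width_px, target_height_px, fill = 0) {
  stopifnot(inherits(image, "image_record"))
  if (target_width_px < image$width_px || target_height_px < image$height_px)
    stop("pad target smaller than image")
  px <- image$pixels
  if (!is.null(px)) {
    out <- matrix(fill, nrow = target_height_px, ncol = target_width_px)
    out[seq_len(image$height_px), seq_len(image$width_px)] <- px
    px <- out
  }
  list(image = image_record(px, id = image$id,
                            width_px = as.integer(target_width_px),
                            height_px = as.integer(target_height_px),
                            calibration = image$calibration),
       boxes = boxes)
}

#' Split a padded image into tiles, remapping boxes
#'
#' Cuts the image into non-overlapping tiles in row-major order. Each box is
#' assigned to every tile it intersects, clipped to the tile and translated
#' to tile-local coordinates; clipped fragments retaining less than
#' `spec$min_box_retention` of the original area are dropped (and reported
#' in the `dropped` attribute). Tile ids are `"<parent id>_t<index>"`.
#'
#' @param image an [image_record()] whose size equals the padded size
#'   (pixels optional).
#' @param boxes box data.frame in image coordinates.
#' @param spec a [tiling_spec()].
#' @return List of `list(image =, boxes =)` per tile, with an attribute
#'   `dropped` holding the box fragments removed by the retention rule.
#' @export
split_tiles <- function(image, boxes, spec = tiling_spec()) {
  stopifnot(inherits(image, "image_record"), inherits(spec, "tiling_spec"))
  tw <- spec$tile_width_px; th <- spec$tile_height_px
  if (image$width_px %% tw != 0 || image$height_px %% th != 0)
    stop("image dimensions not divisible by tile size; apply pad_to() first")
  ncols <- image$width_px %/% tw
  nrows <- image$height_px %/% th
  orig_area <- box_area(boxes)
  dropped <- list()
  tiles <- vector("list", nrows * ncols)
  idx <- 0L
  for (r in seq_len(nrows) - 1L) {
    for (cc in seq_len(ncols) - 1L) {
      idx <- idx + 1L
      x0 <- cc * tw; y0 <- r * th
      px <- image$pixels
      if (!is.null(px)) px <- px[y0 + seq_len(th), x0 + seq_len(tw), drop = FALSE]
      b <- boxes
      if (nrow(b)) {
        b$.orig_area <- orig_area
        b$xmin <- b$xmin - x0; b$xmax <- b$xmax - x0
        b$ymin <- b$ymin - y0; b$ymax <- b$ymax - y0
        b$xmin <- pmax(b$xmin, 0); b$ymin <- pmax(b$ymin, 0)
        b$xmax <- pmin(b$xmax, tw); b$ymax <- pmin(b$ymax, th)
        inside <- b$xmax > b$xmin & b$ymax > b$ymin
        b <- b[inside, , drop = FALSE]
        keep <- box_area(b) >= spec$min_box_retention * b$.orig_area
        if (any(!keep)) {
          d <- b[!keep, , drop = FALSE]
          d$tile <- idx
          dropped[[length(dropped) + 1L]] <- d
        }
        b <- b[keep, , drop = FALSE]
        b$.orig_area <- NULL
        rownames(b) <- NULL
      }
      tiles[[idx]] <- list(
        image = image_record(px, id = sprintf("%s_t%d", image$id, idx),
                             width_px = tw, height_px = th,
                             calibration = image$calibration),
        boxes = b)
    }
  }
  attr(tiles, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else NULL
  tiles
}

#' Prepare detector training tiles from an annotation set
#'
#' Applies resize, pad and split (see [tiling_spec()]) to every image in the
#' set and reassembles the tiled dataset. When `images` (a named list of
#' [image_record()]s keyed by image id) is supplied, tile pixel data are
#' returned alongside; otherwise only the annotation geometry is
#' transformed.
#'
#' @param set an [annotation_set()].
#' @param spec a [tiling_spec()].
#' @param images optional named list of [image_record()]s.
#' @return `list(set =, images =)`: the tiled [annotation_set()] and, when
#'   pixels were supplied, the named list of tile [image_record()]s.
#' @export
prepare_training_tiles <- function(set, spec = tiling_spec(), images = NULL) {
  stopifnot(inherits(set, "annotation_set"))
  out_images <- list(); out_boxes <- list(); out_tiles <- list()
  for (i in seq_len(nrow(set$images))) {
    id <- set$images$id[i]
    img <- if (!is.null(images) && !is.null(images[[id]])) images[[id]] else
      image_record(NULL, id = id, width_px = set$images$width_px[i],
                   height_px = set$images$height_px[i])
    step <- resize_with_boxes(img, boxes_for(set, id), spec$resize_factor)
    step <- pad_to(step$image, step$boxes,
                   spec$padded_width_px, spec$padded_height_px)
    tiles <- split_tiles(step$image, step$boxes, spec)
    for (tl in tiles) {
      out_images[[length(out_images) + 1L]] <-
        data.frame(id = tl$image$id, width_px = tl$image$width_px,
                   height_px = tl$image$height_px, stringsAsFactors = FALSE)
      if (nrow(tl$boxes))
        out_boxes[[length(out_boxes) + 1L]] <-
          cbind(image_id = tl$image$id, tl$boxes)
      if (!is.null(tl$image$pixels)) out_tiles[[tl$image$id]] <- tl$image
    }
  }
  images_df <- do.call(rbind, out_images)
  boxes_df_all <- if (length(out_boxes)) do.call(rbind, out_boxes) else
    cbind(image_id = character(), empty_boxes())
  list(set = annotation_set(images_df, boxes_df_all, set$categories),
       images = if (length(out_tiles)) out_tiles else NULL)
}
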