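#' Annotation set: images plus their boxes
#'
#' Container pairing an image registry with ground-truth or predicted
#' bounding boxes, the in-memory form of a COCO object-detection dataset.
#'
#' @param images data.frame with columns `id` (character), `width_px`,
#'   `height_px`.
#' @param boxes box data.frame (see [boxes_df()]) with an extra `image_id`
#'   column; every `image_id` must appear in `images$id`.
#' @param categories data.frame with columns `id` (integer) and `name`.
#' @return An object of class `"annotation_set"`.
#' @examples
#' imgs <- data.frame(id = "a", width_px = 100, height_px = 80)
#' bx <- cbind(image_id = "a", boxes_df(10, 20, 40, 60))
#' annotation_set(imgs, bx)
#' @export
annotation_set <- function(images,
                           boxes = cbind(image_id = character(), empty_boxes()),
                           categories = data.frame(id = 1L, name = "stoma")) {
  stopifnot(is.data.frame(images),
            all(c("id", "width_px", "height_px") %in% names(images)))
  images$id <- as.character(images$id)
  if (nrow(boxes)) {
    stopifnot("image_id" %in% names(boxes))
    boxes$image_id <- as.character(boxes$image_id)
    unknown <- setdiff(unique(boxes$image_id), images$id)
    if (length(unknown))
      stop("boxes reference unknown image id(s): ",
           paste(head(unknown, 3), collapse = ", "))
    for (id in unique(boxes$image_id)) {
      validate_boxes(boxes[boxes$image_id == id, , drop = FALSE], where = id)
    }
  }
  structure(list(images = images, boxes = boxes, categories = categories),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d image(s), %d box(es), %d categorie(s)\n",
              nrow(x$images), nrow(x$boxes), nrow(x$categories)))
  invisible(x)
}

#' Boxes belonging to one image
#'
#' @param set an [annotation_set()].
#' @param image_id image identifier.
#' @return The box data.frame for that image (without the `image_id` column).
#' @export
boxes_for <- function(set, image_id) {
  stopifnot(inherits(set, "annotation_set"))
  if (!image_id %in% set$images$id) stop("unknown image id: ", image_id)
  b <- set$boxes[set$boxes$image_id == image_id, , drop = FALSE]
  rownames(b) <- NULL
  b[, setdiff(names(b), "image_id"), drop = FALSE]
}

#' Split an annotation set into per-image box tables
#'
#' @param set an [annotation_set()].
#' @return Named list of box data.frames, one element per image id.
#' @export
boxes_by_image <- function(set) {
  stopifnot(inherits(set, "annotation_set"))
  out <- lapply(set$images$id, function(id) boxes_for(set, id))
  names(out) <- set$images$id
  out
}
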