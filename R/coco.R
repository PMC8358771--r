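#' Read a COCO object-detection JSON file
#'
#' Parses the standard `images` / `annotations` / `categories` layout. COCO
#' boxes `[x, y, width, height]` are converted to the package's corner
#' convention at the boundary (`xmax = x + w`, `ymax = y + h`). An optional
#' per-annotation `score` field (as written by [write_coco()] for scored
#' sets) is preserved so the round-trip is lossless.
#'
#' @param path path to a COCO JSON file.
#' @return An [annotation_set()].
#' @seealso [write_coco()], [load_predictions()] for the COCO results format.
#' @export
read_coco <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (key in c("images", "annotations", "categories")) {
    if (is.null(js[[key]])) stop("COCO file missing required key: ", key)
  }
  images <- do.call(rbind, lapply(js$images, function(im) {
    if (is.null(im$file_name) || is.null(im$width) || is.null(im$height))
      stop("COCO image entry missing file_name/width/height")
    data.frame(id = as.character(im$file_name),
               width_px = as.integer(im$width),
               height_px = as.integer(im$height),
               stringsAsFactors = FALSE)
  }))
  if (is.null(images))
    images <- data.frame(id = character(), width_px = integer(),
                         height_px = integer())
  id_of <- images$id
  names(id_of) <- vapply(js$images, function(im) as.character(im$id), "")

  categories <- do.call(rbind, lapply(js$categories, function(ct) {
    data.frame(id = as.integer(ct$id), name = as.character(ct$name),
               stringsAsFactors = FALSE)
  }))
  if (is.null(categories)) categories <- data.frame(id = 1L, name = "stoma")

  boxes <- do.call(rbind, lapply(js$annotations, function(an) {
    bb <- as.numeric(unlist(an$bbox))
    img <- id_of[[as.character(an$image_id)]]
    if (is.null(img)) stop("annotation references unknown image id ", an$image_id)
    if (length(bb) != 4L || bb[3] <= 0 || bb[4] <= 0)
      stop("box with nonpositive width/height [image ", img, "]")
    cat_name <- categories$name[match(as.integer(an$category_id), categories$id)]
    data.frame(image_id = img,
               xmin = bb[1], ymin = bb[2],
               xmax = bb[1] + bb[3], ymax = bb[2] + bb[4],
               score = if (is.null(an$score)) NA_real_ else as.numeric(an$score),
               label = cat_name, stringsAsFactors = FALSE)
  }))
  if (is.null(boxes)) boxes <- cbind(image_id = character(), empty_boxes())
  annotation_set(images, boxes, categories)
}

#' Write an annotation set as COCO object-detection JSON
#'
#' Image ids become integer indices with `file_name` carrying the string id,
#' so [read_coco()] recovers the original identifiers. Non-`NA` scores are
#' written as a per-annotation `score` field (COCO readers ignore unknown
#' fields); for the official scored results layout use
#' [write_coco_results()].
#'
#' @param set an [annotation_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coco <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  img_index <- seq_len(nrow(set$images))
  names(img_index) <- set$images$id
  images <- lapply(img_index, function(i) {
    list(id = unname(i), file_name = set$images$id[i],
         width = set$images$width_px[i], height = set$images$height_px[i])
  })
  categories <- lapply(seq_len(nrow(set$categories)), function(i) {
    list(id = set$categories$id[i], name = set$categories$name[i])
  })
  b <- set$boxes
  annotations <- lapply(seq_len(nrow(b)), function(i) {
    an <- list(id = i,
               image_id = unname(img_index[[b$image_id[i]]]),
               category_id = set$categories$id[match(b$label[i],
                                                     set$categories$name)],
               bbox = c(b$xmin[i], b$ymin[i],
                        b$xmax[i] - b$xmin[i], b$ymax[i] - b$ymin[i]),
               area = (b$xmax[i] - b$xmin[i]) * (b$ymax[i] - b$ymin[i]),
               iscrowd = 0L)
    if (!is.na(b$score[i])) an$score <- b$score[i]
    an
  })
  jsonlite::write_json(
    list(images = unname(images), annotations = annotations,
         categories = categories),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write scored detections in COCO results format
#'
#' The results format is a flat JSON array of
#' `{image_id, category_id, bbox, score}` records referencing the image ids
#' of an accompanying ground-truth file.
#'
#' @param set an [annotation_set()] whose boxes carry scores.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_coco_results <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  b <- set$boxes
  recs <- lapply(seq_len(nrow(b)), function(i) {
    list(image_id = b$image_id[i],
         category_id = set$categories$id[match(b$label[i], set$categories$name)],
         bbox = c(b$xmin[i], b$ymin[i],
                  b$xmax[i] - b$xmin[i], b$ymax[i] - b$ymin[i]),
         score = if (is.na(b$score[i])) 1 else b$score[i])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load external model predictions from COCO results JSON
#'
#' Ingests scored detections (e.g. the output of a trained detector) against
#' a known image registry. Records referencing image ids absent from the
#' registry are rejected.
#'
#' @param path path to a COCO results JSON array.
#' @param images either an [annotation_set()] or its `images` data.frame,
#'   defining the known image ids.
#' @return An [annotation_set()] holding the scored predictions.
#' @export
load_predictions <- function(path, images) {
  if (inherits(images, "annotation_set")) images <- images$images
  stopifnot(is.data.frame(images), all(c("id") %in% names(images)))
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  boxes <- do.call(rbind, lapply(recs, function(r) {
    bb <- as.numeric(unlist(r$bbox))
    img <- as.character(r$image_id)
    if (!img %in% images$id) stop("prediction references unknown image id: ", img)
    if (length(bb) != 4L || bb[3] <= 0 || bb[4] <= 0)
      stop("box with nonpositive width/height [image ", img, "]")
    data.frame(image_id = img, xmin = bb[1], ymin = bb[2],
               xmax = bb[1] + bb[3], ymax = bb[2] + bb[4],
               score = as.numeric(r$score), label = "stoma",
               stringsAsFactors = FALSE)
  }))
  if (is.null(boxes)) boxes <- cbind(image_id = character(), empty_boxes())
  annotation_set(images, boxes)
}

#' Read a Labelbox-style export
#'
#' Parses the minimal dialect documented here, not any particular Labelbox
#' schema version: a JSON array with one record per image, each carrying
#' `"External ID"` (the image id), top-level `image_width` / `image_height`
#' in pixels, and `Label$objects`, a list of rectangle objects with a
#' `bbox` of `top` / `left` / `height` / `width` in pixels. Objects without
#' a `bbox` (other geometry types) are skipped with a warning; records
#' without image dimensions are an error.
#'
#' @param path path to the export JSON.
#' @return An [annotation_set()] in the corner convention
#'   (`xmin = left`, `ymin = top`, `xmax = left + width`,
#'   `ymax = top + height`).
#' @export
read_labelbox <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  images <- list(); boxes <- list()
  for (r in recs) {
    id <- r[["External ID"]]
    if (is.null(id)) id <- r[["external_id"]]
    if (is.null(id)) stop("Labelbox record without an External ID")
    if (is.null(r$image_width) || is.null(r$image_height))
      stop("Labelbox record for image ", id, " lacks image_width/image_height")
    images[[length(images) + 1L]] <-
      data.frame(id = as.character(id),
                 width_px = as.integer(r$image_width),
                 height_px = as.integer(r$image_height),
                 stringsAsFactors = FALSE)
    objs <- r$Label$objects
    if (is.null(objs)) objs <- list()
    for (ob in objs) {
      if (is.null(ob$bbox)) {
        warning("skipping non-rectangle object in image ", id)
        next
      }
      bb <- ob$bbox
      boxes[[length(boxes) + 1L]] <-
        data.frame(image_id = as.character(id),
                   xmin = as.numeric(bb$left), ymin = as.numeric(bb$top),
                   xmax = as.numeric(bb$left) + as.numeric(bb$width),
                   ymax = as.numeric(bb$top) + as.numeric(bb$height),
                   score = NA_real_,
                   label = if (is.null(ob$title)) "stoma" else as.character(ob$title),
                   stringsAsFactors = FALSE)
    }
  }
  images <- if (length(images)) do.call(rbind, images) else
    data.frame(id = character(), width_px = integer(), height_px = integer())
  boxes <- if (length(boxes)) do.call(rbind, boxes) else
    cbind(image_id = character(), empty_boxes())
  labels <- unique(boxes$label)
  categories <- if (length(labels))
    data.frame(id = seq_along(labels), name = labels) else
    data.frame(id = 1L, name = "stoma")
  annotation_set(images, boxes, categories)
}
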