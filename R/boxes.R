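#' Construct a bounding-box table
#'
#' Boxes are corner-based (`xmin`, `ymin`, `xmax`, `ymax`) in pixels with
#' origin at the top-left, x rightward, y downward, half-open `[min, max)`.
#' An optional detection `score` in `[0, 1]` and a category `label` complete
#' each row. All box-consuming functions in the package accept this
#' data.frame layout.
#'
#' @param xmin,ymin,xmax,ymax numeric vectors of corner coordinates (px).
#' @param score detection scores in `[0, 1]`, `NA` for ground truth.
#' @param label category label, recycled.
#' @return A data.frame with columns `xmin, ymin, xmax, ymax, score, label`.
#' @examples
#' boxes_df(c(10, 100), c(20, 50), c(40, 180), c(60, 100))
#' @export
boxes_df <- function(xmin = numeric(), ymin = numeric(),
                     xmax = numeric(), ymax = numeric(),
                     score = NA_real_, label = "stoma") {
  n <- length(xmin)
  df <- data.frame(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
                   xmax = as.numeric(xmax), ymax = as.numeric(ymax),
                   score = rep_len(as.numeric(score), n),
                   label = rep_len(label, n),
                   stringsAsFactors = FALSE)
  validate_boxes(df)
  df
}

#' Validate a bounding-box table
#'
#' Checks the column layout and the geometric invariants
#' (`xmin < xmax`, `ymin < ymax`, coordinates non-negative, scores in
#' `[0, 1]` when present).
#'
#' @param boxes a box data.frame as produced by [boxes_df()].
#' @param where optional context (e.g. an image id) used in error messages.
#' @return `boxes`, invisibly, if valid; otherwise an error.
#' @export
validate_boxes <- function(boxes, where = NULL) {
  needed <- c("xmin", "ymin", "xmax", "ymax")
  ctx <- if (is.null(where)) "" else sprintf(" [image %s]", where)
  if (!is.data.frame(boxes) || !all(needed %in% names(boxes)))
    stop("boxes must be a data.frame with columns xmin, ymin, xmax, ymax", ctx)
  if (nrow(boxes) == 0L) return(invisible(boxes))
  bad <- boxes$xmin >= boxes$xmax | boxes$ymin >= boxes$ymax
  if (any(bad))
    stop(sprintf("box with nonpositive width/height at row %d%s",
                 which(bad)[1L], ctx))
  if (any(boxes$xmin < 0 | boxes$ymin < 0))
    stop("box coordinates must be >= 0", ctx)
  if ("score" %in% names(boxes)) {
    s <- boxes$score[!is.na(boxes$score)]
    if (length(s) && any(s < 0 | s > 1)) stop("scores must lie in [0, 1]", ctx)
  }
  invisible(boxes)
}

#' Empty bounding-box table
#' @return A zero-row [boxes_df()].
#' @export
empty_boxes <- function() boxes_df()

#' Box areas in square pixels
#' @param boxes a box data.frame.
#' @return Numeric vector of `(xmax - xmin) * (ymax - ymin)`.
#' @export
box_area <- function(boxes) {
  (boxes$xmax - boxes$xmin) * (boxes$ymax - boxes$ymin)
}

#' Intersection-over-union between two sets of boxes
#'
#' IoU is the intersection area divided by the union area; 0 for disjoint
#' boxes, 1 for identical boxes, and symmetric in its arguments.
#'
#' @param a,b box data.frames with `m` and `n` rows.
#' @return An `m x n` numeric matrix of pairwise IoU values in `[0, 1]`.
#' @examples
#' a <- boxes_df(0, 0, 10, 10)
#' b <- boxes_df(5, 5, 15, 15)
#' box_iou(a, b)  # 25 / 175
#' @export
box_iou <- function(a, b) {
  m <- nrow(a); n <- nrow(b)
  if (m == 0L || n == 0L) return(matrix(numeric(), m, n))
  ix <- pmax(0, outer(a$xmax, b$xmax, pmin) - outer(a$xmin, b$xmin, pmax))
  iy <- pmax(0, outer(a$ymax, b$ymax, pmin) - outer(a$ymin, b$ymin, pmax))
  inter <- ix * iy
  union <- outer(box_area(a), box_area(b), `+`) - inter
  out <- inter / union
  out[union <= 0] <- 0
  out
}

#' Clip boxes to a rectangle
#'
#' Intersects each box with `[0, width) x [0, height)` and drops boxes whose
#' clipped area is zero.
#'
#' @param boxes a box data.frame.
#' @param width_px,height_px clip rectangle dimensions.
#' @return The clipped box data.frame.
#' @export
clip_boxes <- function(boxes, width_px, height_px) {
  if (nrow(boxes) == 0L) return(boxes)
  boxes$xmin <- pmax(boxes$xmin, 0)
  boxes$ymin <- pmax(boxes$ymin, 0)
  boxes$xmax <- pmin(boxes$xmax, width_px)
  boxes$ymax <- pmin(boxes$ymax, height_px)
  keep <- boxes$xmax > boxes$xmin & boxes$ymax > boxes$ymin
  boxes[keep, , drop = FALSE]
}
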