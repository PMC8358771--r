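test_that("resize scales pixels and boxes together", {
  img <- image_record(NULL, id = "x", width_px = 3072L, height_px = 2048L)
  b <- boxes_df(100, 100, 150, 130)
  out <- resize_with_boxes(img, b, 0.5)
  expect_equal(out$image$width_px, 1536L)
  expect_equal(out$image$height_px, 1024L)
  expect_equal(unlist(out$boxes[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(xmin = 50, ymin = 50, xmax = 75, ymax = 65))

  ident <- resize_with_boxes(img, b, 1)
  expect_equal(ident$image$width_px, img$width_px)
  expect_equal(ident$boxes, b)

  # applying factor then its inverse recovers the original box coordinates
  back <- resize_with_boxes(out$image, out$boxes, 2)
  expect_equal(unlist(back$boxes[1, c("xmin", "ymin", "xmax", "ymax")]),
               unlist(b[1, c("xmin", "ymin", "xmax", "ymax")]),
               tolerance = 1)
  expect_error(resize_with_boxes(img, b, 1e-6), "zero size")
})

test_that("resize interpolates pixel data bilinearly to the target size", {
  px <- matrix(seq(0, 1, length.out = 64 * 48), nrow = 48, ncol = 64)
  img <- image_record(px, id = "p")
  out <- resize_with_boxes(img, empty_boxes(), 0.5)
  expect_equal(dim(out$image$pixels), c(24, 32))
  expect_equal(mean(out$image$pixels), mean(px), tolerance = 0.01)
})

test_that("padding appends right/bottom black pixels and leaves boxes alone", {
  px <- matrix(0.5, nrow = 4, ncol = 6)
  img <- image_record(px, id = "x")
  b <- boxes_df(1, 1, 3, 2)
  out <- pad_to(img, b, 10, 8)
  expect_equal(dim(out$image$pixels), c(8, 10))
  expect_equal(out$image$pixels[1:4, 1:6], px)
  expect_true(all(out$image$pixels[5:8, ] == 0))
  expect_true(all(out$image$pixels[, 7:10] == 0))
  expect_equal(out$boxes, b)

  same <- pad_to(img, b, 6, 4)
  expect_equal(same$image$pixels, px)
  expect_error(pad_to(img, b, 5, 4), "smaller")
})

test_that("split produces two 1024-tiles from the padded canvas and remaps boxes", {
  img <- image_record(NULL, id = "im", width_px = 2048L, height_px = 1024L)
  b <- boxes_df(c(1050, 100), c(250, 100), c(1100, 160), c(280, 150))
  tiles <- split_tiles(img, b, tiling_spec())
  expect_length(tiles, 2L)
  expect_equal(vapply(tiles, function(t) t$image$id, ""),
               c("im_t1", "im_t2"))
  expect_equal(unlist(tiles[[2]]$boxes[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(xmin = 26, ymin = 250, xmax = 76, ymax = 280))
  expect_equal(nrow(tiles[[1]]$boxes), 1L)

  odd <- image_record(NULL, id = "odd", width_px = 1500L, height_px = 1024L)
  expect_error(split_tiles(odd, empty_boxes(), tiling_spec()), "pad_to")
})

test_that("seam boxes are clipped and kept or dropped by the retention rule", {
  img <- image_record(NULL, id = "im", width_px = 2048L, height_px = 1024L)
  b <- boxes_df(1000, 100, 1050, 140)  # 24/50 in tile 1, 26/50 in tile 2
  tiles <- split_tiles(img, b, tiling_spec(min_box_retention = 0.5))
  expect_equal(nrow(tiles[[1]]$boxes), 0L)   # 48% < 50% dropped
  expect_equal(nrow(tiles[[2]]$boxes), 1L)   # 52% kept
  expect_equal(unlist(tiles[[2]]$boxes[1, c("xmin", "xmax")]),
               c(xmin = 0, xmax = 26))
  dropped <- attr(tiles, "dropped")
  expect_equal(nrow(dropped), 1L)

  # with a permissive threshold both fragments survive
  tiles2 <- split_tiles(img, b, tiling_spec(min_box_retention = 0.1))
  expect_equal(nrow(tiles2[[1]]$boxes) + nrow(tiles2[[2]]$boxes), 2L)
})

test_that("split conserves boxes and keeps tile-local coordinates in range", {
  set.seed(7)
  img <- image_record(NULL, id = "im", width_px = 2048L, height_px = 1024L)
  n <- 40
  x <- runif(n, 0, 1988); y <- runif(n, 0, 964)
  b <- boxes_df(x, y, x + runif(n, 20, 60), y + runif(n, 20, 60))
  spec <- tiling_spec(min_box_retention = 0.5)
  tiles <- split_tiles(img, b, spec)
  emitted <- do.call(rbind, lapply(tiles, `[[`, "boxes"))
  dropped <- attr(tiles, "dropped")
  expect_gte(nrow(emitted) + if (is.null(dropped)) 0L else nrow(dropped), n)
  expect_true(all(emitted$xmin >= 0 & emitted$xmax <= 1024 &
                    emitted$ymin >= 0 & emitted$ymax <= 1024))
  expect_true(all(box_area(emitted) <= max(box_area(b)) + 1e-9))
})

test_that("training-tile preparation yields two tiles per full-size image", {
  n_img <- 12L
  imgs <- data.frame(id = sprintf("raw_%03d", seq_len(n_img)),
                     width_px = 3072L, height_px = 2048L)
  set.seed(11)
  bx <- do.call(rbind, lapply(imgs$id, function(id) {
    x <- runif(5, 0, 2900); y <- runif(5, 0, 1900)
    cbind(image_id = id, boxes_df(x, y, x + 140, y + 90))
  }))
  set <- annotation_set(imgs, bx)
  out <- prepare_training_tiles(set, tiling_spec())
  expect_equal(nrow(out$set$images), 2L * n_img)
  expect_true(all(out$set$images$width_px == 1024L))
  # clipping only ever removes area (boxes were resized by 0.5 first)
  expect_lte(sum(box_area(out$set$boxes)),
             sum(box_area(bx)) * 0.5^2 + 1e-9)

  no_boxes <- annotation_set(imgs[1, , drop = FALSE])
  out2 <- prepare_training_tiles(no_boxes, tiling_spec())
  expect_equal(nrow(out2$set$images), 2L)
  expect_equal(nrow(out2$set$boxes), 0L)
})
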