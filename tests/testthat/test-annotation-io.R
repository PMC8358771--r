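test_that("COCO write/read round-trip is the identity, including scores", {
  imgs <- data.frame(id = c("a", "b"), width_px = c(100L, 200L),
                     height_px = c(80L, 160L))
  bx <- rbind(cbind(image_id = "a", boxes_df(c(10, 30), c(20, 5),
                                             c(40, 60), c(60, 25))),
              cbind(image_id = "b", boxes_df(15, 25, 55, 70, score = 0.8)))
  set <- annotation_set(imgs, bx)
  path <- withr::local_tempfile(fileext = ".json")
  write_coco(set, path)
  back <- read_coco(path)
  expect_equal(back$images$id, set$images$id)
  expect_equal(back$images$width_px, set$images$width_px)
  expect_equal(back$boxes[order(back$boxes$xmin), ],
               set$boxes[order(set$boxes$xmin), ],
               ignore_attr = TRUE)
  expect_equal(back$categories$name, set$categories$name)
})

test_that("COCO xywh converts to corner form and empty sets survive", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    images = list(list(id = 1, file_name = "im", width = 100, height = 100)),
    annotations = list(list(id = 1, image_id = 1, category_id = 1,
                            bbox = c(10, 20, 30, 40), area = 1200,
                            iscrowd = 0)),
    categories = list(list(id = 1, name = "stoma"))
  ), path, auto_unbox = TRUE)
  set <- read_coco(path)
  b <- boxes_for(set, "im")
  expect_equal(unlist(b[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(xmin = 10, ymin = 20, xmax = 40, ymax = 60))

  empty <- annotation_set(data.frame(id = "x", width_px = 10L,
                                     height_px = 10L))
  write_coco(empty, path)
  back <- read_coco(path)
  expect_equal(nrow(back$boxes), 0L)
  expect_equal(back$images$id, "x")
})

test_that("malformed COCO inputs are rejected with the image id", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(images = list(), annotations = list()), path,
                       auto_unbox = TRUE)
  expect_error(read_coco(path), "missing required key")

  jsonlite::write_json(list(
    images = list(list(id = 1, file_name = "bad_img", width = 50, height = 50)),
    annotations = list(list(id = 1, image_id = 1, category_id = 1,
                            bbox = c(10, 10, 0, 5))),
    categories = list(list(id = 1, name = "stoma"))
  ), path, auto_unbox = TRUE)
  expect_error(read_coco(path), "bad_img")
  expect_error(read_coco(withr::local_tempfile(fileext = ".json")),
               "no such file")
})

test_that("Labelbox dialect maps top/left/height/width to corners", {
  path <- withr::local_tempfile(fileext = ".json")
  recs <- list(
    list(`External ID` = "im1", image_width = 200, image_height = 150,
         Label = list(objects = list(
           list(title = "stoma",
                bbox = list(top = 20, left = 10, height = 40, width = 30)),
           list(title = "stoma",
                bbox = list(top = 60, left = 80, height = 20, width = 25)),
           list(title = "stoma",
                bbox = list(top = 100, left = 5, height = 30, width = 30))))),
    list(`External ID` = "im2", image_width = 200, image_height = 150,
         Label = list(objects = list(
           list(title = "stoma",
                bbox = list(top = 5, left = 5, height = 10, width = 10)),
           list(title = "stoma",
                bbox = list(top = 50, left = 50, height = 12, width = 14))))),
    list(`External ID` = "im3", image_width = 200, image_height = 150,
         Label = list(objects = list()))
  )
  jsonlite::write_json(recs, path, auto_unbox = TRUE)
  set <- read_labelbox(path)
  expect_equal(nrow(set$boxes), 5L)          # 3 + 2 + 0, count conserved
  expect_equal(nrow(set$images), 3L)         # empty record keeps its image
  b1 <- boxes_for(set, "im1")
  expect_equal(unlist(b1[1, c("xmin", "ymin", "xmax", "ymax")]),
               c(xmin = 10, ymin = 20, xmax = 40, ymax = 60))
})

test_that("Labelbox records without dimensions error; odd geometry warns", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(list(`External ID` = "im1",
                                 Label = list(objects = list()))),
                       path, auto_unbox = TRUE)
  expect_error(read_labelbox(path), "image_width")

  jsonlite::write_json(list(
    list(`External ID` = "im1", image_width = 100, image_height = 100,
         Label = list(objects = list(
           list(title = "stoma", polygon = list()),
           list(title = "stoma",
                bbox = list(top = 1, left = 1, height = 5, width = 5)))))),
    path, auto_unbox = TRUE)
  expect_warning(set <- read_labelbox(path), "non-rectangle")
  expect_equal(nrow(set$boxes), 1L)
})

test_that("COCO results round-trip scored predictions; unknown ids rejected", {
  imgs <- data.frame(id = "a", width_px = 100L, height_px = 100L)
  preds <- annotation_set(imgs, cbind(image_id = "a",
                                      boxes_df(c(1, 50), c(2, 60),
                                               c(21, 70), c(12, 80),
                                               score = c(0.9, 0.4))))
  path <- withr::local_tempfile(fileext = ".json")
  write_coco_results(preds, path)
  back <- load_predictions(path, imgs)
  expect_equal(back$boxes[order(back$boxes$xmin), ],
               preds$boxes[order(preds$boxes$xmin), ], ignore_attr = TRUE)
  expect_error(load_predictions(path, data.frame(id = "other")),
               "unknown image id")
})
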