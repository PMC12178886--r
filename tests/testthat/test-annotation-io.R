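test_that("csv rows map directly onto annotations", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("image_id,annotator_id,group,x_min,y_min,x_max,y_max,label",
               "img007,expert1,expert,10,20,50,60,live"), path)
  ann <- read_annotations(path, "csv")
  expect_equal(nrow(ann), 1)
  expect_equal(ann$image_id, "img007")
  expect_equal(ann$group, "expert")
  expect_equal(as.numeric(ann[1, c("x_min", "y_min", "x_max", "y_max")]),
               c(10, 20, 50, 60))
  expect_equal(ann$label, "live")
  expect_true(is.na(ann$confidence))
})

test_that("empty files read back as empty annotation tables", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_annotations(make_ann("expert1", 1, 1, 2, 2)[0, ], path, "csv")
  expect_equal(nrow(read_annotations(path, "csv")), 0)

  ypath <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), ypath)
  ann <- read_annotations(ypath, "yolo_txt",
                          class_map = c("0" = "live"),
                          image_id = "i", annotator_id = "expert1",
                          group = "expert",
                          image_width = 100, image_height = 100)
  expect_equal(nrow(ann), 0)
})

test_that("round trips are the identity for csv and coco_json", {
  set.seed(42)
  ann <- do.call(rbind, lapply(1:5, function(i)
    random_ann(20, seed = i, image_id = sprintf("img%02d", i))))
  # sprinkle in model annotations with confidences
  model <- make_ann(rep("model1", 10), 1:10 * 7, 1:10 * 5,
                    1:10 * 7 + 30, 1:10 * 5 + 20,
                    group = "model", confidence = round(runif(10, 0.51, 1), 4))
  ann <- rbind(ann, model)
  for (dialect in c("csv", "coco_json")) {
    path <- withr::local_tempfile(fileext = if (dialect == "csv") ".csv"
                                  else ".json")
    write_annotations(ann, path, dialect)
    back <- read_annotations(path, dialect)
    expect_equal(as.data.frame(back), as.data.frame(ann),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("yolo round trip reproduces coordinates within 0.5 px", {
  set.seed(7)
  n <- 25
  x <- runif(n, 0, 900); y <- runif(n, 0, 700)
  ann <- make_ann(rep("expert2", n), x, y, x + runif(n, 5, 90),
                  y + runif(n, 5, 90),
                  label = sample(c("live", "dead", "unknown"), n, TRUE),
                  image_id = "frame1")
  cmap <- c("0" = "live", "1" = "dead", "2" = "unknown")
  path <- withr::local_tempfile(fileext = ".txt")
  write_annotations(ann, path, "yolo_txt", class_map = cmap,
                    image_width = 1000, image_height = 800)
  back <- read_annotations(path, "yolo_txt", class_map = cmap,
                           image_id = "frame1", annotator_id = "expert2",
                           group = "expert",
                           image_width = 1000, image_height = 800)
  for (col in c("x_min", "y_min", "x_max", "y_max")) {
    expect_lt(max(abs(back[[col]] - ann[[col]])), 0.5)
  }
  expect_equal(back$label, ann$label)
})

test_that("admission filters follow the quality-score and confidence rules", {
  images <- image_records(c("a", "b", "c"), c(1, 3, 4))
  ann <- rbind(
    make_ann("model1", 0, 0, 10, 10, image_id = "b", group = "model",
             confidence = 0.50),               # at cutoff: dropped (strict >)
    make_ann("expert1", 0, 0, 10, 10, image_id = "a"),  # QS 1: dropped
    make_ann("model1", 5, 5, 15, 15, image_id = "c", group = "model",
             confidence = 0.65),               # passes both
    make_ann("expert1", 0, 0, 10, 10, image_id = "b")   # human never cut by CS
  )
  kept <- filter_admissible(ann, images)
  expect_equal(nrow(kept), 2)
  expect_equal(kept$image_id, c("c", "b"))
  expect_equal(kept$annotator_id, c("model1", "expert1"))
})

test_that("filter_admissible is idempotent, order-preserving and shrinking", {
  set.seed(3)
  ann <- do.call(rbind, lapply(1:4, function(i)
    random_ann(15, seed = i, image_id = sprintf("img%02d", i))))
  images <- image_records(sprintf("img%02d", 1:4), c(1, 2, 3, 4))
  ann$annotation_id <- seq_len(nrow(ann))
  once <- filter_admissible(ann, images)
  twice <- filter_admissible(once, images)
  expect_identical(once, twice)
  expect_lte(nrow(once), nrow(ann))
  expect_false(is.unsorted(once$annotation_id))
})

test_that("malformed inputs raise informative errors", {
  images <- image_records("a", 3)
  ann <- make_ann("expert1", 0, 0, 10, 10, image_id = "ghost")
  expect_error(filter_admissible(ann, images), "ghost")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("image_id,annotator_id,group,x_min,y_min,x_max,y_max,label",
               "img1,expert1,expert,10,oops,50,60,live"), bad)
  expect_error(read_annotations(bad, "csv"), "y_min")

  badlab <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("image_id,annotator_id,group,x_min,y_min,x_max,y_max,label",
               "img1,expert1,expert,10,20,50,60,alive"), badlab)
  expect_error(read_annotations(badlab, "csv"), "label")

  ypath <- withr::local_tempfile(fileext = ".txt")
  writeLines("0 0.5 0.5 0.1 0.1", ypath)
  expect_error(
    read_annotations(ypath, "yolo_txt", class_map = c("0" = "live"),
                     image_id = "i", annotator_id = "m", group = "model"),
    "image_width")
})

test_that("image metadata round-trips and validates", {
  images <- image_records(sprintf("img%03d", 1:6), c(0, 1, 2, 3, 4, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_image_metadata(images, path)
  expect_equal(as.data.frame(read_image_metadata(path)),
               as.data.frame(images))
  expect_error(image_records(c("a", "a"), c(2, 3)), "unique")
  expect_error(image_records("a", 7), "quality_score")
})
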