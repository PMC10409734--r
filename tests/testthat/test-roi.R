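# ROI interface: darknet dialect IO, per-leg box selection, naive phantom
# detector.

test_that("darknet row denormalization matches the dialect arithmetic", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("0 0.5 0.5 0.2 0.2", f)
  b <- read_darknet_boxes(f, 100, 100)[[1]]
  expect_equal(b$class_label, "femoral_head")
  expect_equal(c(b$x_min, b$y_min, b$x_max, b$y_max), c(40, 40, 60, 60))
})

test_that("empty darknet file gives an empty list", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), f)
  expect_length(read_darknet_boxes(f, 100, 100), 0)
})

test_that("out-of-range and malformed rows are rejected with line numbers", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0.5 0.5 0.2 0.2", "0 1.5 0.5 0.2 0.2"), f)
  expect_error(read_darknet_boxes(f, 100, 100), "line 2",
               class = "htoplan_input_error")
  writeLines("0 0.5 0.5", f)
  expect_error(read_darknet_boxes(f, 100, 100), "malformed",
               class = "htoplan_input_error")
  writeLines("7 0.5 0.5 0.2 0.2", f)
  expect_error(read_darknet_boxes(f, 100, 100), "class_map",
               class = "htoplan_input_error")
})

test_that("darknet round trip is lossless to 1e-6 normalized units", {
  boxes <- list(
    bounding_box("femoral_head", 10.25, 20.5, 55.75, 66.25, 0.93),
    bounding_box("knee", 30.1, 400.9, 190.2, 480.4, 0.81),
    bounding_box("ankle", 91.01, 665.3, 169.99, 734.2, 0.77))
  f <- withr::local_tempfile(fileext = ".txt")
  write_darknet_boxes(boxes, f, 260, 760)
  back <- read_darknet_boxes(f, 260, 760)
  for (i in seq_along(boxes)) {
    expect_equal(back[[i]]$class_label, boxes[[i]]$class_label)
    expect_equal(back[[i]]$x_min / 260, boxes[[i]]$x_min / 260, tolerance = 1e-6)
    expect_equal(back[[i]]$x_max / 260, boxes[[i]]$x_max / 260, tolerance = 1e-6)
    expect_equal(back[[i]]$y_min / 760, boxes[[i]]$y_min / 760, tolerance = 1e-6)
    expect_equal(back[[i]]$y_max / 760, boxes[[i]]$y_max / 760, tolerance = 1e-6)
  }
})

test_that("select_leg_boxes partitions six boxes into two complete triples", {
  mk <- function(cl, cx, conf = 0.9)
    bounding_box(cl, cx - 10, 100, cx + 10, 130, conf)
  boxes <- list(mk("femoral_head", 60), mk("knee", 62), mk("ankle", 58),
                mk("femoral_head", 190), mk("knee", 188), mk("ankle", 192))
  sel <- select_leg_boxes(boxes, 250)
  expect_named(sel$right, c("femoral_head", "knee", "ankle"))
  expect_named(sel$left, c("femoral_head", "knee", "ankle"))
  expect_length(sel$incomplete, 0)
})

test_that("highest-confidence duplicate box wins", {
  mk <- function(cl, cx, conf) bounding_box(cl, cx - 10, 100, cx + 10, 130, conf)
  boxes <- list(mk("femoral_head", 60, 0.9), mk("knee", 60, 0.9),
                mk("knee", 65, 0.7), mk("ankle", 60, 0.9))
  sel <- select_leg_boxes(boxes, 250)
  expect_equal(sel$right$knee$confidence, 0.9)
  expect_equal(bbox_center(sel$right$knee)[1], 60)
})

test_that("missing class yields an incomplete-leg report, not an error", {
  mk <- function(cl, cx) bounding_box(cl, cx - 10, 100, cx + 10, 130, 0.9)
  boxes <- list(mk("knee", 60), mk("ankle", 60),            # no right head
                mk("femoral_head", 190), mk("knee", 190), mk("ankle", 190))
  sel <- select_leg_boxes(boxes, 250)
  expect_null(sel$right)
  expect_named(sel$left, c("femoral_head", "knee", "ankle"))
  expect_equal(sel$incomplete$right, "femoral_head")
})

test_that("phantom_detector boxes overlap ground truth with IoU >= 0.5", {
  for (seed in c(31, 32, 33)) {
    ph <- render_phantom(sample_specs(1, seed = seed)[[1]])
    det <- phantom_detector(ph$image)
    for (cl in c("femoral_head", "knee", "ankle")) {
      db <- Filter(function(b) b$class_label == cl, det)
      expect_length(db, 1)
      expect_gte(bbox_iou(db[[1]], ph$truth$boxes[[cl]]), 0.5)
    }
  }
})

test_that("phantom_detector fails cleanly on a blank image", {
  expect_error(phantom_detector(matrix(0.05, 200, 100)),
               class = "htoplan_detection_failure")
})
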