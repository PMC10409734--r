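# Circular Hough transform: edge detection, accumulator correctness against
# the brute-force oracle, and femoral head recovery.

test_that("edge_map of a constant image is empty", {
  expect_false(any(edge_map(matrix(0.5, 40, 40))))
})

test_that("edge_map of a bright circle hugs the circle", {
  img <- disk_image(48, 48, 24, 24, 14)
  em <- edge_map(img)
  expect_true(any(em))
  idx <- which(em)
  ey <- (idx - 1) %% 48 + 1; ex <- (idx - 1) %/% 48 + 1
  d <- abs(sqrt((ex - 24)^2 + (ey - 24)^2) - 14)
  # hysteresis keeps a short halo along the diagonals where non-maximum
  # suppression quantizes the direction, but the bulk sits on the circle
  expect_lte(max(d), 3)
  expect_lte(median(d), 1)
})

test_that("edge_map of a column step edge concentrates on that column", {
  img <- matrix(0.1, 40, 40); img[, 21:40] <- 0.9
  em <- edge_map(img)
  cols <- unique(((which(em) - 1) %/% 40) + 1)
  expect_true(all(abs(cols - 20.5) <= 1.5))
})

test_that("hough_accumulate equals the brute-force oracle on small fixtures", {
  fixtures <- list(
    circle_mask(32, 32, 16, 15, 9),
    circle_mask(48, 40, 20, 25, 12),
    {
      # two overlapping circles
      m <- circle_mask(64, 64, 22, 30, 13) | circle_mask(64, 64, 42, 34, 15)
      m
    },
    {
      set.seed(99)  # sparse random edges
      m <- matrix(FALSE, 24, 24); m[sample(24 * 24, 40)] <- TRUE
      m
    })
  for (edges in fixtures) {
    r_min <- 5; r_max <- 16
    hr <- hough_accumulate(edges, r_min, r_max)
    bf <- brute_force_hough(edges, r_min, r_max)
    expect_identical(hr$radii, bf$radii)
    expect_equal(unname(hr$accumulator), unname(bf$accumulator))
  }
})

test_that("clean disk centre recovered within 1 px, exact radius", {
  img <- disk_image(60, 60, 29, 31, 17)
  res <- femoral_head_center(img)
  expect_lt(abs(res$center["x"] - 29), 1)
  expect_lt(abs(res$center["y"] - 31), 1)
  expect_equal(res$radius, 17)
})

test_that("disk centre recovered within 2 px under 10% gaussian noise", {
  errs <- vapply(1:20, function(seed) {
    set.seed(seed)
    img <- disk_image(60, 60, 30, 30, 16)
    img <- pmin(pmax(img + matrix(rnorm(3600, 0, 0.1), 60, 60), 0), 1)
    res <- femoral_head_center(img)
    sqrt(sum((res$center - c(30, 30))^2))
  }, numeric(1))
  expect_lte(max(errs), 2)
})

test_that("vote floor triggers a detection failure on weak support", {
  img <- disk_image(60, 60, 30, 30, 16)
  # demanding more support than a full circumference can provide
  expect_error(femoral_head_center(img, vote_floor = 2),
               class = "htoplan_detection_failure")
})

test_that("blank region fails with a detection error, not a crash", {
  expect_error(femoral_head_center(matrix(0.4, 50, 50)),
               class = "htoplan_detection_failure")
})

test_that("bbox radius restriction and offset mapping are honoured", {
  img <- disk_image(200, 120, 60, 70, 25)
  box <- bounding_box("femoral_head", 30, 40, 90, 100)
  crop <- crop_bbox(img, box)
  res <- femoral_head_center(crop, box)
  # restricted radius range still brackets the true radius
  expect_gte(res$radius, 0.5 * 60 / 2)
  expect_lte(res$radius, 60 / 2)
  # centre reported in full-image coordinates
  expect_lt(abs(res$center["x"] - 60), 1)
  expect_lt(abs(res$center["y"] - 70), 1)
})
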