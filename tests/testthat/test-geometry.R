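# Core Miniaci geometry: Fujisawa point, hinge point, ankle centre,
# correction angle, landmark validation and IO.

test_that("fujisawa_point sits 62.5% lateral to the medial edge", {
  f <- fujisawa_point(c(100, 50), c(0, 50))
  expect_equal(unname(f), c(37.5, 50))
  # general fraction and non-horizontal plateau
  f2 <- fujisawa_point(c(10, 8), c(20, 12), frac = 0.25)
  expect_equal(unname(f2), c(12.5, 9))
  expect_error(fujisawa_point(c(1, 1), c(1, 1)),
               class = "htoplan_degenerate_geometry")
})

test_that("hinge_point shifts 14%/18% of knee width from the outer point", {
  # right leg: inner (medial) at larger x
  h <- hinge_point(c(0, 10), c(100, 10))
  expect_equal(unname(h), c(14, 28))
  # left leg mirror: shift goes toward smaller x, still downward
  h2 <- hinge_point(c(100, 10), c(0, 10))
  expect_equal(unname(h2), c(86, 28))
  expect_error(hinge_point(c(5, 0), c(5, 3)),
               class = "htoplan_degenerate_geometry")
  expect_warning(hinge_point(c(100, 10), c(0, 10), laterality = "right"),
                 "unusual")
})

test_that("ankle_center is the talus midpoint", {
  expect_equal(unname(ankle_center(c(10, 20), c(30, 24))), c(20, 22))
  expect_error(ankle_center(c(1, 2), c(1, 2)),
               class = "htoplan_degenerate_geometry")
})

test_that("correction_angle is zero for an aligned leg", {
  lm <- leg_landmarks(
    femoral_head_center = c(150, 50),
    medial_plateau_edge = c(200, 430), lateral_plateau_edge = c(100, 430),
    # Fujisawa x = 200 - 0.625*100 = 137.5; put the ankle centre exactly on
    # the head->Fujisawa line extended to y = 700
    talus_inner = c(200 - 0.625 * 100 + (137.5 - 150) / (430 - 50) * 270 + 27, 700),
    talus_outer = c(200 - 0.625 * 100 + (137.5 - 150) / (430 - 50) * 270 - 27, 700),
    laterality = "right")
  plan <- correction_angle(lm)
  expect_s3_class(plan, "correction_plan")
  expect_equal(plan$correction_angle_deg, 0, tolerance = 1e-12)
})

test_that("correction_angle sign follows the deformity direction", {
  base <- function(ankle_x) leg_landmarks(
    femoral_head_center = c(150, 50),
    medial_plateau_edge = c(200, 430), lateral_plateau_edge = c(100, 430),
    talus_inner = c(ankle_x + 27, 700), talus_outer = c(ankle_x - 27, 700),
    laterality = "right")
  # varus: ankle medial (larger x for a right leg) of the correction axis
  expect_gt(correction_angle(base(180))$correction_angle_deg, 0)
  # valgus: ankle lateral of the correction axis
  expect_lt(correction_angle(base(80))$correction_angle_deg, 0)
})

test_that("correction_angle honours an explicit ground level", {
  lm <- leg_landmarks(
    femoral_head_center = c(150, 50),
    medial_plateau_edge = c(200, 430), lateral_plateau_edge = c(100, 430),
    talus_inner = c(207, 700), talus_outer = c(153, 700),
    laterality = "right")
  p1 <- correction_angle(lm)
  expect_equal(p1$ground_level_y, 700)
  p2 <- correction_angle(lm, ground_level_y = 760)
  expect_equal(p2$ground_level_y, 760)
  expect_false(isTRUE(all.equal(p1$correction_angle_deg,
                                p2$correction_angle_deg)))
  expect_error(correction_angle(lm, ground_level_y = 40),
               class = "htoplan_degenerate_geometry")
})

test_that("worked example: plan on caption-style inputs is reproducible", {
  # a varus right leg in phantom proportions; angle recomputed from scratch
  lm <- leg_landmarks(
    femoral_head_center = c(140, 65),
    medial_plateau_edge = c(186, 430), lateral_plateau_edge = c(74, 430),
    talus_inner = c(197, 700), talus_outer = c(143, 700),
    laterality = "right")
  plan <- correction_angle(lm)
  # independent recomputation of the same construction
  fw <- lm$fujisawa_point
  t <- (700 - 65) / (fw["y"] - 65)
  G <- c(140 + t * (fw["x"] - 140), 700)
  hp <- lm$hinge_point
  u <- lm$ankle_center - hp; v <- G - hp
  ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  expect_equal(abs(plan$correction_angle_deg), unname(ang), tolerance = 1e-12)
})

test_that("landmark validation rejects inconsistent sets", {
  ok <- leg_landmarks(
    femoral_head_center = c(150, 50),
    medial_plateau_edge = c(200, 430), lateral_plateau_edge = c(100, 430),
    talus_inner = c(207, 700), talus_outer = c(153, 700),
    laterality = "right")
  expect_silent(validate_leg_landmarks(ok))
  # Fujisawa off the plateau segment
  bad <- ok; bad$fujisawa_point <- pt(150, 400)
  expect_error(validate_leg_landmarks(bad), class = "htoplan_input_error")
  # laterality mismatch: medial at smaller x claimed to be a right leg
  bad2 <- ok
  tmp <- bad2$medial_plateau_edge
  bad2$medial_plateau_edge <- bad2$lateral_plateau_edge
  bad2$lateral_plateau_edge <- tmp
  bad2$fujisawa_point <- fujisawa_point(bad2$medial_plateau_edge,
                                        bad2$lateral_plateau_edge)
  expect_error(validate_leg_landmarks(bad2), class = "htoplan_input_error")
})

test_that("landmark CSV and JSON round trip", {
  lm <- leg_landmarks(
    femoral_head_center = c(150.25, 50.5),
    medial_plateau_edge = c(200.1, 430.3), lateral_plateau_edge = c(100.4, 430.9),
    talus_inner = c(207.7, 700.2), talus_outer = c(153.3, 700.8),
    laterality = "right")
  for (ext in c("csv", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", ext))
    write_landmarks(lm, f)
    back <- read_landmarks(f)[[1]]
    for (nm in LANDMARK_POINTS)
      expect_equal(back[[nm]], lm[[nm]], tolerance = 1e-9)
    expect_identical(back$laterality, "right")
  }
})

test_that("mechanical_axis_angle is signed from vertical", {
  lm <- leg_landmarks(
    femoral_head_center = c(150, 50),
    medial_plateau_edge = c(200, 430), lateral_plateau_edge = c(100, 430),
    talus_inner = c(177, 700), talus_outer = c(123, 700),
    laterality = "right")
  expect_equal(mechanical_axis_angle(lm), 0)
  lm2 <- lm; lm2$ankle_center <- pt(215, 700)
  expect_equal(mechanical_axis_angle(lm2),
               atan2(65, 650) * 180 / pi, tolerance = 1e-12)
})
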