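# Phantom generator: determinism, ground-truth consistency, noise models,
# fixture round trips.

test_that("with_seed is deterministic and restores the RNG state", {
  set.seed(123); before <- runif(1)
  set.seed(123)
  a <- with_seed(9, runif(3))
  after <- runif(1)
  expect_identical(a, with_seed(9, runif(3)))
  expect_identical(before, after)  # outer stream untouched
})

test_that("rendering the same spec twice gives identical images and truth", {
  sp <- phantom_spec(angle_deg = 9, noise = list(type = "gaussian", sigma = 0.03),
                     seed = 5)
  p1 <- render_phantom(sp); p2 <- render_phantom(sp)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$truth, p2$truth)
})

test_that("correction angle of the truth landmarks equals the requested angle", {
  for (seed in c(61, 62, 63)) {
    sp <- sample_specs(1, seed = seed)[[1]]
    ph <- render_phantom(sp)
    plan <- correction_angle(ph$truth$landmarks)
    expect_equal(plan$correction_angle_deg, sp$angle_deg, tolerance = 1e-6)
  }
})

test_that("left phantoms mirror right phantoms about the vertical midline", {
  r <- render_phantom(phantom_spec(angle_deg = 10, laterality = "right", seed = 2))
  l <- render_phantom(phantom_spec(angle_deg = 10, laterality = "left", seed = 2))
  w1 <- r$truth$landmarks$femoral_head_center["x"]
  w2 <- l$truth$landmarks$femoral_head_center["x"]
  expect_equal(unname(w1 + w2), 260, tolerance = 1e-9)  # symmetric about width/2
  expect_equal(unname(r$truth$landmarks$femoral_head_center["y"]),
               unname(l$truth$landmarks$femoral_head_center["y"]))
})

test_that("truth boxes contain their landmarks", {
  ph <- render_phantom(sample_specs(1, seed = 64)[[1]])
  tr <- ph$truth
  inside <- function(p, b)
    p["x"] >= b$x_min && p["x"] <= b$x_max && p["y"] >= b$y_min && p["y"] <= b$y_max
  expect_true(inside(tr$landmarks$femoral_head_center, tr$boxes$femoral_head))
  expect_true(inside(tr$landmarks$medial_plateau_edge, tr$boxes$knee))
  expect_true(inside(tr$landmarks$lateral_plateau_edge, tr$boxes$knee))
  expect_true(inside(tr$landmarks$talus_inner, tr$boxes$ankle))
  expect_true(inside(tr$landmarks$talus_outer, tr$boxes$ankle))
})

test_that("gaussian noise perturbs the image but keeps it in [0, 1]", {
  sp0 <- phantom_spec(angle_deg = 8, seed = 3)
  spn <- phantom_spec(angle_deg = 8, seed = 3,
                      noise = list(type = "gaussian", sigma = 0.08))
  i0 <- render_phantom(sp0)$image
  i1 <- render_phantom(spn)$image
  expect_gt(mean(abs(i1 - i0)), 0.01)
  expect_true(all(i1 >= 0 & i1 <= 1))
})

test_that("sampled correction angles follow the skew-normal target", {
  specs <- sample_specs(400, seed = 17)
  angles <- vapply(specs, function(s) s$angle_deg, numeric(1))
  expect_true(all(angles >= 0 & angles <= 30))
  # reference: large direct draw from the same truncated distribution
  ref <- with_seed(99, {
    x <- rskewnorm(2e5, 6, 5, 4)
    x[x >= 0 & x <= 30]
  })
  se <- sqrt(stats::var(angles) / length(angles) + stats::var(ref) / length(ref))
  expect_lt(abs(mean(angles) - mean(ref)), 3 * se)
  expect_gt(mean((angles - mean(angles))^3) / stats::sd(angles)^3, 0)  # right skew
})

test_that("fixture directories round trip through the sidecar readers", {
  dir <- withr::local_tempdir()
  specs <- sample_specs(2, seed = 71)
  write_phantom_fixtures(specs, dir)
  img <- read_radiograph(file.path(dir, "phantom_001.png"))
  expect_equal(dim(img), c(760, 260))
  boxes <- read_darknet_boxes(file.path(dir, "phantom_001.txt"), 260, 760)
  expect_setequal(vapply(boxes, function(b) b$class_label, character(1)),
                  c("femoral_head", "knee", "ankle"))
  truth <- jsonlite::read_json(file.path(dir, "phantom_001_truth.json"))
  expect_equal(truth$correction_angle_deg, specs[[1]]$angle_deg,
               tolerance = 1e-9)
})

test_that("invalid spec and distribution arguments are rejected", {
  expect_error(phantom_spec(angle_deg = -4), class = "htoplan_input_error")
  expect_error(sample_specs(3, angle_distribution = list(type = "cauchy")),
               class = "htoplan_input_error")
})
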