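# Active Appearance Model: triangulation, texture model, fixed point,
# recovery, failure semantics.

test_that("Delaunay triangulation of a unit square gives two triangles", {
  pts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  tri <- htoplan:::delaunay_triangulate(pts)
  expect_equal(nrow(tri), 2)
  expect_true(all(tri >= 1 & tri <= 4))
  area <- function(ix) {
    p <- pts[ix, ]
    abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
        (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
  }
  expect_equal(sum(apply(tri, 1, area)), 1, tolerance = 1e-12)
})

test_that("barycentric coordinates sum to one and reconstruct the point", {
  a <- c(0, 0); b <- c(4, 1); cc <- c(1, 5); p <- c(2, 2)
  l <- htoplan:::barycentric(p, a, b, cc)
  expect_equal(sum(l), 1, tolerance = 1e-12)
  expect_equal(l[1] * a + l[2] * b + l[3] * cc, p, tolerance = 1e-12)
})

test_that("normalized textures have zero mean and unit standard deviation", {
  set.seed(2)
  g <- htoplan:::normalize_texture(runif(200))
  expect_equal(mean(g), 0, tolerance = 1e-12)
  expect_equal(stats::sd(g), 1, tolerance = 1e-12)
  expect_identical(htoplan:::normalize_texture(rep(3, 10)), rep(0, 10))
})

test_that("trained texture model is orthonormal and projects out residuals", {
  aam <- trained_aam(17)
  M <- aam$tex_modes
  expect_equal(crossprod(M), diag(ncol(M)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # residual of the mean texture is exactly zero
  expect_equal(max(abs(htoplan:::aam_residual(aam, aam$tex_mean))), 0)
  # any residual is orthogonal to the texture subspace
  set.seed(4)
  r <- htoplan:::aam_residual(aam, aam$tex_mean + rnorm(length(aam$tex_mean)))
  expect_lt(max(abs(crossprod(M, r))), 1e-8)
})

test_that("fit from ground truth stays within 0.5 px RMS (fixed point)", {
  aam <- trained_aam(31)
  case <- phantom_case(230, 31)
  f <- fit_aam(case$crop, aam, case$gt)
  expect_lte(shape_rms(f$shape, case$gt), 0.5)
})

test_that("fit recovers a 5 px translated init within 1.5 px RMS", {
  aam <- trained_aam(31)
  for (seed in c(201, 205, 209)) {
    case <- phantom_case(seed, 31)
    init <- case$gt; init[, 1] <- init[, 1] + 5
    f <- fit_aam(case$crop, aam, init)
    expect_lte(shape_rms(f$shape, case$gt), 1.5)
  }
})

test_that("blank image reports converged = FALSE without an exception", {
  aam <- trained_aam(17)
  blank <- matrix(0.5, 90, 140)
  init <- htoplan:::init_shape_for_bbox(aam$shape_model,
                                        bounding_box("knee", 20, 20, 120, 80))
  f <- fit_aam(blank, aam, init)
  expect_false(f$converged)
  expect_true(is.matrix(f$shape))
  expect_true(is.finite(f$residual))
})

test_that("fitting is deterministic", {
  aam <- trained_aam(17)
  case <- phantom_case(216, 17)
  init <- case$gt; init[, 1] <- init[, 1] + 5
  f1 <- fit_aam(case$crop, aam, init)
  f2 <- fit_aam(case$crop, aam, init)
  expect_identical(f1$shape, f2$shape)
})

test_that("training rejects mismatched or insufficient inputs", {
  ts <- training_set(17)
  expect_error(train_aam(ts$images[1:3], ts$shapes[1:2]),
               class = "htoplan_input_error")
  expect_error(train_aam(ts$images[1], ts$shapes[1]),
               class = "htoplan_input_error")
})
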