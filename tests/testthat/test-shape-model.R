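# Procrustes alignment, PCA shape model, pose recovery, serialization.

random_shapes <- function(n, n_points, seed) {
  set.seed(seed)
  base <- knee_shape_template(n_points, outer = c(10, 20), inner = c(120, 18))
  lapply(seq_len(n), function(i) {
    th <- runif(1, -0.2, 0.2); s <- runif(1, 0.8, 1.2)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    sh <- base %*% t(R) * s
    sh + matrix(rnorm(2, 0, 10), nrow(sh), 2, byrow = TRUE) +
      matrix(rnorm(length(sh), 0, 0.5), nrow(sh), 2)
  })
}

test_that("procrustes_align matches the naive alternating oracle to 1e-9", {
  shapes <- random_shapes(8, 17, seed = 3)
  ga <- procrustes_align(shapes)
  # package normalizes to unit centroid size = sqrt(sum of squared coords)
  oracle <- naive_gpa(shapes)
  # the mean is defined up to rotation; align oracle mean onto package mean
  al <- htoplan:::align_centered(oracle$mean, ga$mean)
  expect_lt(max(abs(al - ga$mean)), 1e-9)
})

test_that("mean shape has unit centroid size and zero centroid", {
  ga <- procrustes_align(random_shapes(6, 31, seed = 5))
  expect_equal(colMeans(ga$mean), c(x = 0, y = 0), tolerance = 1e-12)
  expect_equal(htoplan:::centroid_size(ga$mean), 1, tolerance = 1e-12)
})

test_that("PCA modes are orthonormal with non-increasing variances", {
  sm <- train_shape_model(random_shapes(10, 31, seed = 7))
  M <- sm$modes
  expect_equal(crossprod(M), diag(ncol(M)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(sm$variances) <= 1e-12))
})

test_that("full-variance model reconstructs every training shape exactly", {
  shapes <- random_shapes(6, 17, seed = 9)
  sm <- train_shape_model(shapes, variance_fraction = 1)
  for (s in shapes) {
    rec <- htoplan:::project_to_shape_space(sm, s, clamp = Inf)$shape
    expect_lt(max(abs(rec - s)), 1e-8)
  }
})

test_that("identical training shapes give a zero-variance model", {
  s <- knee_shape_template(17, c(10, 20), c(120, 18))
  sm <- train_shape_model(list(s, s, s))
  expect_true(all(sm$variances < 1e-20))
})

test_that("pose recovery: a similarity-transformed mean is recovered exactly", {
  sm <- train_shape_model(random_shapes(8, 17, seed = 11))
  mu <- sm$mean_shape
  pose <- c(a = 80 * cos(0.3), b = 80 * sin(0.3), tx = 40, ty = 260)
  pts <- htoplan:::pose_apply(pose, mu)
  pr <- htoplan:::project_to_shape_space(sm, pts)
  expect_equal(unname(pr$pose), unname(pose), tolerance = 1e-9)
  expect_lt(max(abs(pr$shape - pts)), 1e-8)
  expect_true(all(abs(pr$b) < 1e-8))
})

test_that("mode coefficients are clamped to three standard deviations", {
  shapes <- random_shapes(10, 17, seed = 13)
  sm <- train_shape_model(shapes)
  mu <- sm$mean_shape
  # push far along mode 1 (in the model frame), then project
  v <- htoplan:::shape_to_vec(mu) + 10 * sqrt(sm$variances[1]) * sm$modes[, 1]
  pr <- htoplan:::project_to_shape_space(sm, htoplan:::vec_to_shape(v))
  expect_lte(abs(pr$b[1]), 3 * sqrt(sm$variances[1]) + 1e-9)
})

test_that("knee_points picks the indexed characteristic points", {
  s <- knee_shape_template(31, c(10, 20), c(120, 18))
  im <- list(outer = attr(s, "outer_index"), inner = attr(s, "inner_index"))
  kp <- knee_points(s, im)
  expect_equal(unname(kp$outer), unname(s[im$outer, ]))
  expect_equal(unname(kp$inner), unname(s[im$inner, ]))
})

test_that("knee model serialization round trips to working models", {
  asm <- trained_asm(17)
  aam <- trained_aam(17)
  fa <- withr::local_tempfile(fileext = ".json")
  fs <- withr::local_tempfile(fileext = ".json")
  write_knee_model(aam, fa); write_knee_model(asm, fs)
  aam2 <- read_knee_model(fa); asm2 <- read_knee_model(fs)
  case <- phantom_case(301, 17)
  init <- case$gt; init[, 1] <- init[, 1] + 4
  f1 <- fit_aam(case$crop, aam, init); f2 <- fit_aam(case$crop, aam2, init)
  expect_lt(max(abs(f1$shape - f2$shape)), 1e-9)
  g1 <- fit_asm(case$crop, asm, init); g2 <- fit_asm(case$crop, asm2, init)
  expect_lt(max(abs(g1$shape - g2$shape)), 1e-9)
  expect_error(read_knee_model(withr::local_tempfile(fileext = ".json")),
               class = "htoplan_input_error")
})
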