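# Agreement statistics: ICC against the ANOVA oracle and frozen external
# reference values, Bland-Altman identities, skew-normal recovery.

random_table <- function(seed) {
  set.seed(seed)
  n <- sample(8:40, 1); k <- sample(2:6, 1)
  truth <- runif(n, 0, 20)
  sapply(seq_len(k), function(j) truth + rnorm(1, 0, 1) + rnorm(n, 0, runif(1, 0.2, 2)))
}

test_that("ICC matches the explicit two-way ANOVA oracle to 1e-10", {
  for (seed in 1:50) {
    m <- random_table(seed)
    expect_equal(icc(m, "ICC2")$icc, aov_icc2(m), tolerance = 1e-10)
    expect_equal(icc(m, "ICC3")$icc, aov_icc3(m), tolerance = 1e-10)
  }
})

test_that("ICC point estimates, intervals and p-value match frozen external references", {
  # Independently computed with a reference implementation of the
  # Shrout-Fleiss two-way ICC (absolute and consistency, single rater)
  # on this exact table.
  set.seed(42)
  truth <- runif(25, 4, 18)
  m <- cbind(r1 = truth + rnorm(25, 0.2, 0.6),
             r2 = truth + rnorm(25, -0.1, 0.5),
             r3 = truth + rnorm(25, 0, 0.7))
  a <- icc(m, "ICC2")
  expect_equal(a$icc, 0.980902651366, tolerance = 1e-10)
  expect_equal(a$ci_low, 0.954173945730, tolerance = 1e-9)
  expect_equal(a$ci_high, 0.991785242245, tolerance = 1e-9)
  expect_equal(a$p_value, 9.676316643e-41, tolerance = 1e-6)
  b <- icc(m, "ICC3")
  expect_equal(b$icc, 0.985827035979, tolerance = 1e-10)
  expect_equal(b$ci_low, 0.972693548569, tolerance = 1e-9)
  expect_equal(b$ci_high, 0.993260105926, tolerance = 1e-9)
})

test_that("perfectly anti-correlated raters give ICC(3,1) of exactly -1", {
  set.seed(1)
  x <- rnorm(200)
  expect_equal(icc(cbind(x, -x), "ICC3")$icc, -1)
})

test_that("ICC(3,1) ignores constant per-rater offsets; ICC(2,1) does not", {
  m <- random_table(7)
  shifted <- sweep(m, 2, seq_len(ncol(m)) * 2, "+")
  expect_equal(icc(shifted, "ICC3")$icc, icc(m, "ICC3")$icc, tolerance = 1e-10)
  expect_lt(icc(shifted, "ICC2")$icc, icc(m, "ICC2")$icc)
})

test_that("degenerate rating tables are rejected", {
  expect_error(icc(matrix(3, 10, 3)), class = "htoplan_input_error")
  expect_error(icc(matrix(1:4, 2, 2)), class = "htoplan_input_error")  # n < 3
  expect_error(icc(cbind(1:10)), class = "htoplan_input_error")        # k < 2
  m <- random_table(9); m[1, 1] <- NA
  expect_error(icc(m), class = "htoplan_input_error")
})

test_that("bland_altman of a series with itself is exactly zero", {
  set.seed(11)
  a <- runif(30, 0, 25)
  ba <- bland_altman(a, a)
  expect_identical(ba$bias, 0)
  expect_identical(ba$sd_diff, 0)
  expect_identical(ba$loa_low, 0)
  expect_identical(ba$loa_high, 0)
})

test_that("bland_altman recovers a known bias and limits", {
  set.seed(12)
  b <- runif(500, 5, 20)
  a <- b + 1.5 + rnorm(500, 0, 0.5)
  ba <- bland_altman(a, b)
  expect_equal(ba$bias, mean(a - b))
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * sd(a - b))
  expect_gt(ba$within_loa, 0.9)
})

test_that("error_summary and mean_observer compute what they claim", {
  es <- error_summary(c(1, 2, 5), c(0, 4, 5))
  expect_equal(es, list(median = 1, mean = 1, min = 0, max = 2))
  expect_equal(mean_observer(cbind(c(1, 3), c(3, 5))), c(2, 4))
  expect_error(error_summary(1:3, 1:4), class = "htoplan_input_error")
})

test_that("agreement_report combines ICC, Bland-Altman and error fields", {
  set.seed(13)
  b <- runif(25, 2, 20); a <- b + rnorm(25, 0, 0.4)
  rep <- agreement_report(a, b)
  expect_s3_class(rep, "agreement_report")
  expect_equal(rep$bias, mean(a - b))
  expect_equal(rep$errors$max, max(abs(a - b)))
  expect_gt(rep$icc, 0.9)
})

test_that("skew-normal density integrates to one and alpha = 0 is normal", {
  x <- seq(-30, 50, by = 0.01)
  expect_equal(sum(dskewnorm(x, 6, 5, 4)) * 0.01, 1, tolerance = 1e-4)
  expect_equal(dskewnorm(x, 2, 3, 0), dnorm(x, 2, 3), tolerance = 1e-12)
})

test_that("skew-normal fit recovers parameters at n = 5000", {
  y <- with_seed(2, rskewnorm(5000, 6, 5, 4))
  f <- fit_skew_normal(y)
  expect_lt(abs(f$location - 6), 0.5)
  expect_lt(abs(f$scale - 5) / 5, 0.2)
  expect_lt(abs(f$shape - 4) / 4, 0.2)
  expect_lt(abs(f$mean - mean(y)), 3 * sd(y) / sqrt(length(y)))
})

test_that("skew-normal fit of normal data drives the shape toward zero", {
  z <- with_seed(3, rnorm(5000, 10, 2))
  f <- fit_skew_normal(z)
  expect_lt(abs(f$shape), 0.5)
  expect_lt(abs(f$mean - 10), 3 * 2 / sqrt(5000))
})

test_that("constant or tiny samples are rejected by the skew-normal fit", {
  expect_error(fit_skew_normal(rep(5, 50)), class = "htoplan_input_error")
  expect_error(fit_skew_normal(1:5), class = "htoplan_input_error")
})

test_that("rating tables read from CSV drop the id column", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = 1:6, r1 = c(1:6) + 0.1, r2 = c(1:6) - 0.2),
            f, row.names = FALSE)
  m <- read_rating_table(f)
  expect_equal(colnames(m), c("r1", "r2"))
  expect_equal(dim(m), c(6, 2))
})
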