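# Agreement and error statistics: two-way intraclass correlation with
# F-based confidence interval, Bland-Altman limits of agreement, absolute
# error summaries, and skew-normal fits of correction-angle distributions.

check_rating_table <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m) || any(!is.finite(m)))
    stop_input("rating table must be all-finite numeric")
  if (ncol(m) < 2 || nrow(m) < 3)
    stop_input("rating table needs >= 2 raters and >= 3 subjects")
  m
}

#' Intraclass correlation coefficient between raters
#'
#' Default is the two-way random-effects, single-rater, absolute-agreement
#' form ICC(2,1): subjects and raters are both random, and systematic rater
#' offsets count against agreement — appropriate when asking whether raters
#' (or an algorithm and a rater) can be used interchangeably. The consistency
#' form ICC(3,1) (raters fixed, offsets ignored) is also available. The 95%
#' confidence interval uses the F-distribution method and the p-value tests
#' ICC = 0 via F = MSR/MSE.
#'
#' @param table Matrix or data frame: rows subjects, columns raters.
#' @param form `"ICC2"` (absolute agreement, default) or `"ICC3"`
#'   (consistency), both single-rater.
#' @param conf_level Confidence level for the interval.
#' @return An `agreement_report` with `icc`, `ci_low`, `ci_high`, `p_value`,
#'   the mean squares, and the form used.
#' @export
icc <- function(table, form = c("ICC2", "ICC3"), conf_level = 0.95) {
  form <- match.arg(form)
  m <- check_rating_table(table)
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)       # between subjects
  ssc <- n * sum((col_m - grand)^2)       # between raters
  sse <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr <= 0 && mse <= 0)
    stop_input("zero between-subject variance: ICC undefined")
  alpha <- 1 - conf_level
  if (form == "ICC2") {
    est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    # Shrout-Fleiss F-method interval via the Satterthwaite df
    fj <- msc / mse
    vn <- (k - 1) * (n - 1) *
      (k * est * fj + n * (1 + (k - 1) * est) - k * est)^2
    vd <- (n - 1) * k^2 * est^2 * fj^2 +
      (n * (1 + (k - 1) * est) - k * est)^2
    v <- vn / vd
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    upper <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    fobs <- msr / mse
    f_l <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    f_u <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lower <- (f_l - 1) / (f_l + k - 1)
    upper <- (f_u - 1) / (f_u + k - 1)
  }
  fobs <- msr / mse
  p <- stats::pf(fobs, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  structure(list(icc = est, ci_low = lower, ci_high = upper, p_value = p,
                 form = form, n_subjects = n, n_raters = k,
                 mean_squares = c(MSR = msr, MSC = msc, MSE = mse),
                 conf_level = conf_level),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("%s intraclass correlation: %.3f (%.0f%% CI %.3f-%.3f), p = %.3g\n",
              x$form, x$icc, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$p_value))
  cat(sprintf("  %d subjects x %d raters\n", x$n_subjects, x$n_raters))
  if (!is.null(x$bias))
    cat(sprintf("  Bland-Altman bias %.3f, limits of agreement [%.3f, %.3f]\n",
                x$bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman agreement between two angle series
#'
#' @param a,b Numeric vectors of equal length (degrees).
#' @param z Multiplier for the limits of agreement (1.96 for 95% limits; no
#'   small-sample t correction unless supplied).
#' @return List with `bias` (`mean(a - b)`), `loa_low`, `loa_high`,
#'   `sd_diff`, and `within_loa` (fraction of differences inside the limits).
#' @export
bland_altman <- function(a, b, z = 1.96) {
  if (length(a) != length(b)) stop_input("series lengths differ")
  if (length(a) < 2) stop_input("need >= 2 paired values")
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  lo <- bias - z * s; hi <- bias + z * s
  list(bias = bias, loa_low = lo, loa_high = hi, sd_diff = s,
       mean = (a + b) / 2, diff = d,
       within_loa = mean(d >= lo & d <= hi))
}

#' Absolute-difference error summary
#'
#' @param pred,ref Numeric vectors of equal length.
#' @return Named list: `median`, `mean`, `min`, `max` of `|pred - ref|`.
#' @export
error_summary <- function(pred, ref) {
  if (length(pred) != length(ref)) stop_input("series lengths differ")
  if (!length(pred)) stop_input("empty series")
  e <- abs(pred - ref)
  list(median = stats::median(e), mean = mean(e), min = min(e), max = max(e))
}

#' Row-wise mean observer
#'
#' @param table Rating matrix (rows subjects, columns raters, >= 2 raters).
#' @return Numeric vector of row means.
#' @export
mean_observer <- function(table) {
  m <- as.matrix(table)
  if (ncol(m) < 2) stop_input("mean observer needs >= 2 raters")
  rowMeans(m)
}

#' Combined agreement report for two series
#'
#' ICC (treating the two series as raters), Bland-Altman bias and limits,
#' and the absolute-error summary, in one object.
#'
#' @param a,b Angle series of equal length.
#' @param ... Passed to [icc()].
#' @return An `agreement_report` with Bland-Altman and error-summary fields
#'   added.
#' @export
agreement_report <- function(a, b, ...) {
  rep <- icc(cbind(a = a, b = b), ...)
  ba <- bland_altman(a, b)
  rep$bias <- ba$bias; rep$loa_low <- ba$loa_low; rep$loa_high <- ba$loa_high
  rep$errors <- error_summary(a, b)
  rep
}

# --- skew-normal -------------------------------------------------------------

#' Skew-normal density, sampling and maximum-likelihood fit
#'
#' The skew-normal with location `xi`, scale `omega > 0` and shape `alpha`
#' has density `2/omega * phi(z) * Phi(alpha * z)`, `z = (x - xi)/omega`;
#' `alpha = 0` recovers the normal. Used to describe the right-skewed
#' distribution of planned correction angles.
#'
#' @param x Quantiles.
#' @param xi,omega,alpha Location, scale (> 0), shape.
#' @param log Return log-density?
#' @return `dskewnorm`: densities; `rskewnorm`: samples; `fit_skew_normal`:
#'   a `skew_normal_fit` with the ML parameters and log-likelihood.
#' @export
dskewnorm <- function(x, xi = 0, omega = 1, alpha = 0, log = FALSE) {
  if (omega <= 0) stop_input("omega must be positive")
  z <- (x - xi) / omega
  ld <- log(2) - log(omega) + stats::dnorm(z, log = TRUE) +
    stats::pnorm(alpha * z, log.p = TRUE)
  if (log) ld else exp(ld)
}

#' @rdname dskewnorm
#' @param n Number of samples.
#' @export
rskewnorm <- function(n, xi = 0, omega = 1, alpha = 0) {
  # Azzalini's representation: |U| correlated with V via delta
  delta <- alpha / sqrt(1 + alpha^2)
  u <- stats::rnorm(n); v <- stats::rnorm(n)
  z <- delta * abs(u) + sqrt(1 - delta^2) * v
  xi + omega * z
}

skew_normal_mean <- function(xi, omega, alpha) {
  xi + omega * alpha / sqrt(1 + alpha^2) * sqrt(2 / pi)
}

#' @rdname dskewnorm
#' @param angles Sample to fit (>= 10 values, non-constant).
#' @return `fit_skew_normal`: object of class `skew_normal_fit`.
#' @export
fit_skew_normal <- function(angles) {
  if (length(angles) < 10) stop_input("need >= 10 samples for a skew-normal fit")
  s <- stats::sd(angles)
  if (s == 0) stop_input("constant data: skew-normal scale would be zero")
  # moment-based start: map sample skewness to delta
  g1 <- mean((angles - mean(angles))^3) / s^3
  g1 <- sign(g1) * min(abs(g1), 0.99)
  d2 <- (pi / 2) * abs(g1)^(2 / 3) / (abs(g1)^(2 / 3) + ((4 - pi) / 2)^(2 / 3))
  delta <- sign(g1) * sqrt(min(d2, 0.995))
  a0 <- delta / sqrt(max(1 - delta^2, 1e-6))
  om0 <- s / sqrt(max(1 - 2 * delta^2 / pi, 0.05))
  xi0 <- mean(angles) - om0 * delta * sqrt(2 / pi)
  nll <- function(p) {
    if (p[2] <= 0) return(1e10)
    v <- -sum(dskewnorm(angles, p[1], p[2], p[3], log = TRUE))
    if (!is.finite(v)) 1e10 else v
  }
  fit <- stats::optim(c(xi0, om0, a0), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  refit <- stats::optim(fit$par, nll, method = "BFGS",
                        control = list(maxit = 500))
  if (refit$value <= fit$value) fit <- refit
  if (!is.finite(fit$value) || fit$value >= 1e10)
    stop_input("skew-normal fit failed to converge (nll = %g)", fit$value)
  structure(list(location = fit$par[1], scale = fit$par[2],
                 shape = fit$par[3], loglik = -fit$value,
                 mean = skew_normal_mean(fit$par[1], fit$par[2], fit$par[3]),
                 n = length(angles)),
            class = "skew_normal_fit")
}

#' @export
print.skew_normal_fit <- function(x, ...) {
  cat(sprintf(
    "Skew-normal fit (n = %d): location %.3f, scale %.3f, shape %.3f; mean %.3f, logLik %.2f\n",
    x$n, x$location, x$scale, x$shape, x$mean, x$loglik))
  invisible(x)
}

#' Read a rating table CSV
#'
#' Expects a header row of rater names and one row per leg/image; an
#' optional first column named `id` is dropped.
#'
#' @param path CSV path.
#' @return Numeric matrix, columns named after raters.
#' @export
read_rating_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (tolower(names(df)[1]) %in% c("id", "image", "leg"))
    df <- df[, -1, drop = FALSE]
  check_rating_table(as.matrix(df))
}
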