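# Shared test helpers: memoized phantom training sets / trained models
# (expensive, reused across files) and independent reference oracles.

.htoplan_test_cache <- new.env(parent = emptyenv())

cached <- function(key, make) {
  if (is.null(.htoplan_test_cache[[key]]))
    assign(key, make(), envir = .htoplan_test_cache)
  .htoplan_test_cache[[key]]
}

training_set <- function(n_points, n = 20, seed = 11) {
  cached(sprintf("ts_%d_%d_%d", n_points, n, seed),
         function() phantom_training_set(n, n_points = n_points, seed = seed))
}

trained_asm <- function(n_points) {
  cached(sprintf("asm_%d", n_points), function() {
    ts <- training_set(n_points)
    train_asm(ts$images, ts$shapes, index_map = ts$index_map)
  })
}

trained_aam <- function(n_points) {
  cached(sprintf("aam_%d", n_points), function() {
    ts <- training_set(n_points)
    train_aam(ts$images, ts$shapes, index_map = ts$index_map)
  })
}

# one rendered phantom with its knee-crop ground truth, by seed
phantom_case <- function(seed, n_points) {
  sp <- sample_specs(1, seed = seed)[[1]]
  ph <- render_phantom(sp)
  crop <- crop_bbox(ph$image, ph$truth$boxes$knee)
  off <- attr(crop, "offset")
  gt <- phantom_knee_shape(sp, n_points)
  gt[, 1] <- gt[, 1] - off[1]
  gt[, 2] <- gt[, 2] - off[2]
  list(spec = sp, phantom = ph, crop = crop, offset = off, gt = gt)
}

shape_rms <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# O(N * |edges|) brute-force circular Hough accumulator: for every center
# (a, b) and integer radius r, count edge pixels whose rounded distance
# equals r. Matches the layout of hough_accumulate ([b, a, r]).
brute_force_hough <- function(edges, r_min, r_max) {
  radii <- as.numeric(seq(ceiling(r_min), floor(r_max)))
  h <- nrow(edges); w <- ncol(edges)
  idx <- which(edges)
  ey <- (idx - 1L) %% h + 1L
  ex <- (idx - 1L) %/% h + 1L
  acc <- array(0L, c(h, w, length(radii)))
  for (b in seq_len(h)) for (a in seq_len(w)) {
    d <- round(sqrt((ex - a)^2 + (ey - b)^2))
    for (k in seq_along(radii)) acc[b, a, k] <- sum(d == radii[k])
  }
  list(accumulator = acc, radii = radii)
}

# Naive generalized-Procrustes oracle: alternating minimization with
# explicit rotation/scale least squares on coordinates (no complex
# arithmetic), same normalization conventions as procrustes_align.
naive_gpa <- function(shapes, tol = 1e-12, max_iter = 200) {
  centered <- lapply(shapes, function(s) {
    s <- sweep(s, 2, colMeans(s))
    s / sqrt(sum(s^2))
  })
  fit_sim <- function(z, w) {
    # minimize ||c(R z) - w||^2 over scaled rotation [a -b; b a]
    den <- sum(z^2)
    a <- sum(z[, 1] * w[, 1] + z[, 2] * w[, 2]) / den
    b <- sum(z[, 1] * w[, 2] - z[, 2] * w[, 1]) / den
    cbind(a * z[, 1] - b * z[, 2], b * z[, 1] + a * z[, 2])
  }
  mean_shape <- centered[[1]]
  for (it in seq_len(max_iter)) {
    aligned <- lapply(centered, fit_sim, w = mean_shape)
    nm <- Reduce(`+`, aligned) / length(aligned)
    nm <- sweep(nm, 2, colMeans(nm))
    nm <- nm / sqrt(sum(nm^2))
    if (max(abs(nm - mean_shape)) < tol) { mean_shape <- nm; break }
    mean_shape <- nm
  }
  list(mean = mean_shape, aligned = lapply(centered, fit_sim, w = mean_shape))
}

# Explicit two-way ANOVA mean squares through stats::aov, for the ICC oracle
aov_icc2 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  av <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  msr <- av["subject", "Mean Sq"]
  msc <- av["rater", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

aov_icc3 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  av <- summary(stats::aov(y ~ subject + rater, data = df))[[1]]
  msr <- av["subject", "Mean Sq"]
  mse <- av["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse)
}

# rasterized circle edge mask
circle_mask <- function(h, w, cx, cy, r, thickness = 0.6) {
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  abs(sqrt((xs - cx)^2 + (ys - cy)^2) - r) <= thickness
}

# filled bright disk image
disk_image <- function(h, w, cx, cy, r, fg = 0.9, bg = 0.1) {
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  img <- matrix(bg, h, w)
  img[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- fg
  img
}
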