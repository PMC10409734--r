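# Statistical shape models of the knee contour.
#
# Shapes are n x 2 matrices of (x, y) landmark positions, ordered along the
# proximal tibia contour; the characteristic outer and inner knee points sit
# at fixed indices (see knee_shape_template). Training aligns the shapes by
# generalized Procrustes analysis and applies PCA to the aligned residuals.

shape_as_matrix <- function(s) {
  m <- as.matrix(s)
  if (ncol(m) != 2 || !is.numeric(m) || any(!is.finite(m)))
    stop_input("a shape must be a finite n x 2 matrix")
  m
}

shape_to_vec <- function(s) c(s[, 1], s[, 2])
vec_to_shape <- function(v) {
  n <- length(v) / 2
  cbind(x = v[seq_len(n)], y = v[n + seq_len(n)])
}

centroid_size <- function(s) {
  c0 <- colMeans(s)
  sqrt(sum((s[, 1] - c0[1])^2 + (s[, 2] - c0[2])^2))
}

# similarity aligning centered shape z to centered target w (complex LS)
align_centered <- function(z, w) {
  zc <- complex(real = z[, 1], imaginary = z[, 2])
  wc <- complex(real = w[, 1], imaginary = w[, 2])
  a <- sum(Conj(zc) * wc) / sum(Mod(zc)^2)
  out <- a * zc
  cbind(x = Re(out), y = Im(out))
}

#' Generalized Procrustes alignment of landmark shapes
#'
#' Centres and unit-size-scales every shape, then iteratively aligns each to
#' the current mean by a least-squares similarity transform and re-estimates
#' the mean (renormalized to unit centroid size) until the mean moves less
#' than `tol` or `max_iter` rounds.
#'
#' @param shapes List of n x 2 matrices, all of the same length.
#' @param tol Mean-movement convergence threshold.
#' @param max_iter Iteration cap.
#' @return List with `aligned` (list of aligned shapes), `mean` (unit-size
#'   mean shape), `mean_size` (average centroid size of the input shapes)
#'   and `iterations`.
#' @export
procrustes_align <- function(shapes, tol = 1e-10, max_iter = 100) {
  if (!length(shapes)) stop_input("need at least one shape")
  shapes <- lapply(shapes, shape_as_matrix)
  n <- nrow(shapes[[1]])
  if (any(vapply(shapes, nrow, 1L) != n))
    stop_input("all shapes must have the same number of points")
  sizes <- vapply(shapes, centroid_size, numeric(1))
  if (any(sizes == 0))
    stop_degenerate("a shape has all points coincident")
  centered <- lapply(shapes, function(s) {
    s <- sweep(s, 2, colMeans(s)); s / centroid_size(s)
  })
  mean_shape <- centered[[1]]
  it <- 0
  repeat {
    it <- it + 1
    aligned <- lapply(centered, align_centered, w = mean_shape)
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    ns <- centroid_size(new_mean)
    if (ns == 0) stop_degenerate("degenerate mean shape")
    new_mean <- new_mean / ns
    moved <- max(abs(new_mean - mean_shape))
    mean_shape <- new_mean
    if (moved < tol || it >= max_iter) break
  }
  aligned <- lapply(centered, align_centered, w = mean_shape)
  list(aligned = aligned, mean = mean_shape, mean_size = mean(sizes),
       iterations = it)
}

#' Train a PCA shape model
#'
#' Aligns the training shapes by [procrustes_align()] and extracts the
#' principal modes of the aligned shape vectors, keeping the smallest number
#' of modes that explains at least `variance_fraction` of the total variance.
#'
#' @param shapes List of n x 2 landmark matrices (>= 2).
#' @param variance_fraction Retained-variance target (default 0.98).
#' @param index_map Named list of characteristic point indices
#'   (`outer`, `inner`); taken from shape attributes when absent.
#' @param laterality Which leg the model describes.
#' @return A `shape_model`: mean shape (aligned frame), orthonormal `modes`
#'   (2n x m), per-mode `variances`, `mean_size`, `n_points`, `index_map`.
#' @export
train_shape_model <- function(shapes, variance_fraction = 0.98,
                              index_map = NULL,
                              laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  if (length(shapes) < 2) stop_input("need at least two training shapes")
  if (is.null(index_map)) {
    a <- attributes(shapes[[1]])
    index_map <- list(outer = a$outer_index %||% 1L,
                      inner = a$inner_index %||% nrow(shape_as_matrix(shapes[[1]])))
  }
  ga <- procrustes_align(shapes)
  # Tangent-space projection: re-express every training shape by the same
  # operation project_to_shape_space applies at fit time (inverse of the
  # least-squares similarity fit of the mean onto the shape), iterating the
  # mean to its fixed point. PCA about that mean then reconstructs every
  # training shape exactly when all modes are kept; PCA on the raw GPA
  # alignments would not, because their unit-size normalization differs
  # from the fit-time scale by a per-shape factor outside the mode span.
  unit <- lapply(shapes, function(s) {
    s <- shape_as_matrix(s)
    s <- sweep(s, 2, colMeans(s))
    s / centroid_size(s)
  })
  m <- ga$mean
  tang <- NULL
  for (it in seq_len(200)) {
    zm <- complex(real = m[, 1], imaginary = m[, 2])
    tang <- lapply(unit, function(sh) {
      zs <- complex(real = sh[, 1], imaginary = sh[, 2])
      beta <- sum(Conj(zs) * zm)
      if (Mod(beta) == 0) stop_degenerate("shape orthogonal to the mean")
      out <- sum(Mod(zm)^2) * zs / Conj(beta)
      cbind(x = Re(out), y = Im(out))
    })
    m_new <- Reduce(`+`, tang) / length(tang)
    done <- max(abs(m_new - m)) < 1e-12
    m <- m_new
    if (done) break
  }
  X <- do.call(rbind, lapply(tang, shape_to_vec))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  cv <- crossprod(Xc) / (nrow(X) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  total <- sum(ev)
  n_modes <- if (total <= 0) 0L else {
    cum <- cumsum(ev) / total
    max(1L, which(cum >= variance_fraction)[1])
  }
  n_modes <- min(n_modes, sum(ev > 1e-12 * max(ev, 1)))
  modes <- if (n_modes > 0) eg$vectors[, seq_len(n_modes), drop = FALSE]
           else matrix(0, ncol(X), 0)
  structure(list(
    mean_shape = vec_to_shape(mu), modes = modes,
    variances = ev[seq_len(n_modes)], total_variance = total,
    mean_size = ga$mean_size, n_points = nrow(ga$mean),
    n_train = length(shapes), variance_fraction = variance_fraction,
    index_map = index_map, laterality = laterality),
    class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf(
    "Shape model: %d landmarks (%s leg), %d training shapes, %d modes (%.0f%% variance)\n",
    x$n_points, x$laterality, x$n_train, length(x$variances),
    100 * x$variance_fraction))
  invisible(x)
}

# --- pose (similarity transform image <-> model frame) -----------------------

pose_apply <- function(pose, s) {
  cbind(x = pose["a"] * s[, 1] - pose["b"] * s[, 2] + pose["tx"],
        y = pose["b"] * s[, 1] + pose["a"] * s[, 2] + pose["ty"])
}

pose_invert <- function(pose) {
  d <- pose["a"]^2 + pose["b"]^2
  a <- pose["a"] / d; b <- -pose["b"] / d
  c(a = unname(a), b = unname(b),
    tx = unname(-(a * pose["tx"] - b * pose["ty"])),
    ty = unname(-(b * pose["tx"] + a * pose["ty"])))
}

# least-squares similarity carrying src onto dst
pose_from_align <- function(src, dst) {
  cs <- colMeans(src); cd <- colMeans(dst)
  zs <- complex(real = src[, 1] - cs[1], imaginary = src[, 2] - cs[2])
  zd <- complex(real = dst[, 1] - cd[1], imaginary = dst[, 2] - cd[2])
  aa <- sum(Conj(zs) * zd) / sum(Mod(zs)^2)
  a <- Re(aa); b <- Im(aa)
  c(a = a, b = b,
    tx = unname(cd[1] - (a * cs[1] - b * cs[2])),
    ty = unname(cd[2] - (b * cs[1] + a * cs[2])))
}

# Project image-frame points onto the model subspace: recover pose and
# clamped mode coefficients, return the regularized image-frame shape.
project_to_shape_space <- function(model, pts, clamp = 3) {
  mu <- model$mean_shape
  # The inverse least-squares pose is exactly the tangent-space projection
  # about the mean — the same convention the training PCA uses — so a
  # full-variance model reproduces its training shapes exactly.
  if (centroid_size(pts) == 0) stop_degenerate("all points coincident: no pose")
  pose <- pose_from_align(mu, pts)
  if (pose["a"]^2 + pose["b"]^2 == 0)
    stop_degenerate("points orthogonal to the mean shape")
  model_pts <- pose_apply(pose_invert(pose), pts)
  dv <- shape_to_vec(model_pts) - shape_to_vec(mu)
  if (length(model$variances)) {
    b <- drop(crossprod(model$modes, dv))
    lim <- clamp * sqrt(pmax(model$variances, 0))
    b <- pmin(pmax(b, -lim), lim)
    rec <- shape_to_vec(mu) + drop(model$modes %*% b)
  } else {
    b <- numeric(0)
    rec <- shape_to_vec(mu)
  }
  list(shape = pose_apply(pose, vec_to_shape(rec)), b = b, pose = pose)
}

# Mean shape placed for fitting: centred on the bounding box, scaled so the
# shape width is `scale_frac` of the box width.
init_shape_for_bbox <- function(model, bbox, scale_frac = 0.8) {
  mu <- model$mean_shape
  wmu <- diff(range(mu[, 1]))
  s <- scale_frac * (bbox$x_max - bbox$x_min) / wmu
  ctr <- bbox_center(bbox)
  out <- mu * s
  sweep(out, 2, colMeans(out)) + matrix(ctr, nrow(mu), 2, byrow = TRUE)
}

#' Extract the characteristic knee points from a fitted shape
#'
#' @param fitted n x 2 fitted shape in image coordinates.
#' @param index_map List with `outer` and `inner` indices (as stored in a
#'   trained model); may also be a `shape_model`/`asm_model`/`aam_model`.
#' @return List with `inner` and `outer` points.
#' @export
knee_points <- function(fitted, index_map) {
  if (inherits(index_map, c("asm_model", "aam_model")))
    index_map <- index_map$shape_model$index_map
  if (inherits(index_map, "shape_model")) index_map <- index_map$index_map
  s <- shape_as_matrix(fitted)
  list(inner = pt(s[index_map$inner, 1], s[index_map$inner, 2]),
       outer = pt(s[index_map$outer, 1], s[index_map$outer, 2]))
}
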