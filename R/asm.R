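# Active Shape Model: per-landmark normal-profile statistics learned from
# training images, fitted by Mahalanobis-minimizing search along the normals
# with shape-space regularization.

# unit normals at each landmark from the contour tangents (closed contour)
shape_normals <- function(s) {
  n <- nrow(s)
  nxt <- s[c(2:n, 1), , drop = FALSE]
  prv <- s[c(n, 1:(n - 1)), , drop = FALSE]
  tang <- nxt - prv
  len <- sqrt(rowSums(tang^2))
  len[len == 0] <- 1
  cbind(-tang[, 2] / len, tang[, 1] / len)
}

# Normalized first-derivative intensity profile at point p along normal nrm:
# intensities sampled at offsets -(k+1)..(k+1), central differences, then
# division by the sum of absolute values. NULL when the profile leaves the
# image (insufficient support).
sample_profile <- function(img, p, nrm, k) {
  off <- seq(-(k + 1), k + 1)
  xs <- p[1] + off * nrm[1]
  ys <- p[2] + off * nrm[2]
  if (any(xs < 1 | xs > ncol(img) | ys < 1 | ys > nrow(img))) return(NULL)
  g <- bilinear_sample(img, xs, ys)
  d <- (g[3:length(g)] - g[1:(length(g) - 2)]) / 2
  s <- sum(abs(d))
  if (s > 0) d / s else d
}

#' Train an Active Shape Model
#'
#' Builds the PCA shape model and, for every landmark, the statistics of the
#' normalized first-derivative gray-level profile sampled along the contour
#' normal (`2k + 1` samples): mean and regularized covariance, whose inverse
#' drives the Mahalanobis search during fitting. Images are histogram
#' equalized before sampling, matching what [fit_asm()] does.
#'
#' @param images List of grayscale matrices, one per shape.
#' @param shapes List of n x 2 landmark matrices.
#' @param k Profile half-width (samples each side of the landmark).
#' @param variance_fraction,index_map,laterality Passed to
#'   [train_shape_model()].
#' @return An `asm_model`: `shape_model`, `profile_mean` ((2k+1) x n),
#'   `profile_icov` (list of inverse covariances), `k`.
#' @export
train_asm <- function(images, shapes, k = 4L, variance_fraction = 0.98,
                      index_map = NULL, laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  if (length(images) != length(shapes))
    stop_input("one shape per image required")
  sm <- train_shape_model(shapes, variance_fraction, index_map, laterality)
  n <- sm$n_points
  plen <- 2 * k + 1
  eq <- lapply(images, equalize_roi)
  prof_mean <- matrix(0, plen, n)
  prof_icov <- vector("list", n)
  for (i in seq_len(n)) {
    samples <- list()
    for (j in seq_along(eq)) {
      s <- shape_as_matrix(shapes[[j]])
      nrm <- shape_normals(s)
      g <- sample_profile(eq[[j]], s[i, ], nrm[i, ], k)
      if (!is.null(g)) samples[[length(samples) + 1]] <- g
    }
    if (!length(samples))
      stop_input("landmark %d has no profile support in any training image", i)
    P <- do.call(rbind, samples)
    mu <- colMeans(P)
    cv <- if (nrow(P) > 1) stats::cov(P) else matrix(0, plen, plen)
    eps <- max(1e-6 * sum(diag(cv)) / plen, 1e-8)
    cv <- cv + diag(eps, plen)
    prof_mean[, i] <- mu
    prof_icov[[i]] <- solve(cv)
  }
  structure(list(shape_model = sm, profile_mean = prof_mean,
                 profile_icov = prof_icov, k = k),
            class = "asm_model")
}

#' @export
print.asm_model <- function(x, ...) {
  cat(sprintf("Active Shape Model: profile half-width %d\n", x$k))
  print(x$shape_model)
  invisible(x)
}

#' Fit an Active Shape Model to an image
#'
#' Iterates two steps: (1) each landmark searches `search_range` positions
#' either side along its normal for the profile with the smallest
#' Mahalanobis distance to its trained profile model; (2) the moved shape is
#' projected back onto the shape subspace with mode coefficients clamped to
#' three standard deviations. Stops when the mean point movement drops below
#' `move_tol` pixels. Landmarks never leave the region of the initial shape
#' expanded by 10% (or the supplied `roi`).
#'
#' @param image Grayscale matrix (the knee region crop); histogram equalized
#'   internally.
#' @param model An `asm_model`.
#' @param init_shape Starting shape in image coordinates (e.g. the mean
#'   shape placed at the bounding-box centre).
#' @param max_iter Iteration cap.
#' @param search_range Search positions each side of a landmark.
#' @param move_tol Convergence threshold on mean point movement (px).
#' @param roi Optional [bounding_box()] limiting landmark movement.
#' @return List with `shape` (n x 2), `converged`, `iterations`,
#'   `mean_movement`.
#' @export
fit_asm <- function(image, model, init_shape, max_iter = 60,
                    search_range = 5L, move_tol = 0.15, roi = NULL) {
  stopifnot(inherits(model, "asm_model"))
  img <- equalize_roi(image)
  s <- shape_as_matrix(init_shape)
  if (nrow(s) != model$shape_model$n_points)
    stop_input("init shape has %d points, model expects %d",
               nrow(s), model$shape_model$n_points)
  lim <- fit_region(init_shape, roi, nrow(image), ncol(image))
  k <- model$k
  m <- search_range
  offs <- -m:m
  order_pref <- order(abs(offs))  # ties resolve toward no movement
  any_signal <- FALSE
  it <- 0; moved <- Inf
  repeat {
    it <- it + 1
    nrm <- shape_normals(s)
    target <- s
    for (i in seq_len(nrow(s))) {
      d <- rep(NA_real_, length(offs))
      for (jj in seq_along(offs)) {
        p <- s[i, ] + offs[jj] * nrm[i, ]
        g <- sample_profile(img, p, nrm[i, ], k)
        if (is.null(g)) next
        r <- g - model$profile_mean[, i]
        d[jj] <- drop(t(r) %*% model$profile_icov[[i]] %*% r)
      }
      if (all(is.na(d))) next
      if (diff(range(d, na.rm = TRUE)) > 1e-12) any_signal <- TRUE
      best <- order_pref[which.min(d[order_pref])]
      target[i, ] <- s[i, ] + offs[best] * nrm[i, ]
    }
    new_s <- project_to_shape_space(model$shape_model, target)$shape
    new_s[, 1] <- pmin(pmax(new_s[, 1], lim$x1), lim$x2)
    new_s[, 2] <- pmin(pmax(new_s[, 2], lim$y1), lim$y2)
    moved <- mean(sqrt(rowSums((new_s - s)^2)))
    s <- new_s
    if (moved < move_tol || it >= max_iter) break
  }
  list(shape = s, converged = any_signal && moved < move_tol,
       iterations = it, mean_movement = moved)
}

# movement limits: supplied ROI, or the initial shape's box, expanded by 10%
fit_region <- function(init_shape, roi, img_h, img_w) {
  if (!is.null(roi)) {
    x1 <- roi$x_min; x2 <- roi$x_max; y1 <- roi$y_min; y2 <- roi$y_max
  } else {
    s <- shape_as_matrix(init_shape)
    x1 <- min(s[, 1]); x2 <- max(s[, 1]); y1 <- min(s[, 2]); y2 <- max(s[, 2])
  }
  mx <- 0.1 * (x2 - x1); my <- 0.1 * (y2 - y1)
  list(x1 = max(1, x1 - mx), x2 = min(img_w, x2 + mx),
       y1 = max(1, y1 - my), y2 = min(img_h, y2 + my))
}
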