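# Active Appearance Model: joint PCA model of shape and of gray-level
# texture in the shape-normalized (mean-shape) frame, fitted by iterative
# texture-residual-driven parameter updates with a step-halving line search.

# --- Delaunay triangulation (Bowyer-Watson) ---------------------------------

# Plain incremental Delaunay for the small landmark sets used here.
delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 3) stop_input("triangulation needs >= 3 points")
  # super-triangle enclosing everything
  cx <- mean(range(pts[, 1])); cy <- mean(range(pts[, 2]))
  d <- max(diff(range(pts[, 1])), diff(range(pts[, 2]))) * 10 + 10
  P <- rbind(pts, c(cx - 2 * d, cy - d), c(cx + 2 * d, cy - d), c(cx, cy + 2 * d))
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), 1)
  circum <- function(tri) {
    a <- P[tri[1], ]; b <- P[tri[2], ]; c <- P[tri[3], ]
    ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
    dd <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(dd) < 1e-12) return(c(Inf, Inf, Inf))
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / dd
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / dd
    c(ux, uy, (ux - ax)^2 + (uy - ay)^2)
  }
  cc <- matrix(circum(tris[1, ]), 1)
  for (ip in seq_len(n)) {
    p <- P[ip, ]
    bad <- which((p[1] - cc[, 1])^2 + (p[2] - cc[, 2])^2 <= cc[, 3] + 1e-9)
    if (!length(bad)) next
    # boundary polygon: edges of bad triangles not shared by two bad triangles
    edges <- NULL
    for (t in bad) {
      tr <- tris[t, ]
      edges <- rbind(edges, tr[c(1, 2)], tr[c(2, 3)], tr[c(3, 1)])
    }
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    keep <- !(key %in% key[duplicated(key)])
    edges <- edges[keep, , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    if (nrow(edges)) {
      newt <- cbind(edges, ip)
      tris <- rbind(tris, newt)
      cc <- rbind(cc, t(apply(newt, 1, circum)))
    }
  }
  keep <- apply(tris, 1, function(tr) all(tr <= n))
  tris <- tris[keep, , drop = FALSE]
  storage.mode(tris) <- "integer"
  unname(tris)
}

barycentric <- function(p, a, b, c) {
  v0 <- b - a; v1 <- c - a; v2 <- p - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  if (abs(den) < 1e-12) return(c(-1, -1, -1))
  v <- (d11 * d20 - d01 * d21) / den
  w <- (d00 * d21 - d01 * d20) / den
  c(1 - v - w, v, w)
}

# reference frame: mean shape scaled/translated to a raster, plus the
# barycentric coordinates of every interior pixel
build_reference_frame <- function(mean_shape, mean_size, ref_scale, margin = 2) {
  ref <- mean_shape * (mean_size * ref_scale)
  ref[, 1] <- ref[, 1] - min(ref[, 1]) + margin + 1
  ref[, 2] <- ref[, 2] - min(ref[, 2]) + margin + 1
  tris <- delaunay_triangulate(ref)
  w <- ceiling(max(ref[, 1])) + margin
  h <- ceiling(max(ref[, 2])) + margin
  px <- integer(0); py <- integer(0); tri <- integer(0)
  bc <- NULL
  for (t in seq_len(nrow(tris))) {
    a <- ref[tris[t, 1], ]; b <- ref[tris[t, 2], ]; c <- ref[tris[t, 3], ]
    xs <- max(1L, floor(min(a[1], b[1], c[1]))):min(w, ceiling(max(a[1], b[1], c[1])))
    ys <- max(1L, floor(min(a[2], b[2], c[2]))):min(h, ceiling(max(a[2], b[2], c[2])))
    for (x in xs) for (y in ys) {
      l <- barycentric(c(x, y), a, b, c)
      if (all(l >= -1e-9)) {
        px <- c(px, x); py <- c(py, y); tri <- c(tri, t)
        bc <- rbind(bc, l)
      }
    }
  }
  # a pixel may fall in two triangles along shared edges; keep the first
  keylin <- px * (h + 1L) + py
  first <- !duplicated(keylin)
  list(points = ref, triangles = tris, width = w, height = h,
       px = px[first], py = py[first], tri = tri[first],
       bary = bc[first, , drop = FALSE])
}

# sample the image texture under `shape` into the reference frame
sample_texture <- function(img, shape, frame) {
  t1 <- frame$triangles[frame$tri, 1]
  t2 <- frame$triangles[frame$tri, 2]
  t3 <- frame$triangles[frame$tri, 3]
  xs <- frame$bary[, 1] * shape[t1, 1] + frame$bary[, 2] * shape[t2, 1] +
    frame$bary[, 3] * shape[t3, 1]
  ys <- frame$bary[, 1] * shape[t1, 2] + frame$bary[, 2] * shape[t2, 2] +
    frame$bary[, 3] * shape[t3, 2]
  bilinear_sample(img, xs, ys)
}

normalize_texture <- function(g) {
  s <- stats::sd(g)
  if (!is.finite(s) || s == 0) return(g * 0)
  (g - mean(g)) / s
}

#' Train an Active Appearance Model
#'
#' Builds the PCA shape model, warps every training image into the
#' mean-shape reference frame by a piecewise-affine map over a Delaunay
#' triangulation of the mean landmarks, applies PCA to the normalized
#' textures, and learns the linear parameter-update matrix by regressing
#' known parameter perturbations (shape modes and pose) against the texture
#' residuals they induce.
#'
#' @param images,shapes Training pairs (>= 2); images are histogram
#'   equalized internally.
#' @param variance_fraction Retained variance for both PCA stages.
#' @param ref_scale Reference-frame scale relative to the mean training
#'   size (controls texture resolution/cost).
#' @param index_map,laterality Passed to [train_shape_model()].
#' @param n_perturb Perturbation magnitudes per parameter during update
#'   training.
#' @return An `aam_model`.
#' @export
train_aam <- function(images, shapes, variance_fraction = 0.98,
                      ref_scale = 0.6, index_map = NULL,
                      laterality = c("right", "left"), n_perturb = 2L) {
  laterality <- match.arg(laterality)
  if (length(images) != length(shapes) || length(images) < 2)
    stop_input("need >= 2 image/shape pairs")
  sm <- train_shape_model(shapes, variance_fraction, index_map, laterality)
  frame <- build_reference_frame(sm$mean_shape, sm$mean_size, ref_scale)
  if (!length(frame$px)) stop_input("texture frame has zero area")
  eq <- lapply(images, equalize_roi)
  shapes <- lapply(shapes, shape_as_matrix)
  G <- do.call(cbind, lapply(seq_along(eq), function(j)
    normalize_texture(sample_texture(eq[[j]], shapes[[j]], frame))))
  tex_mean <- rowMeans(G)
  Gc <- G - tex_mean
  # texture PCA via the Gram matrix (samples << pixels)
  gram <- crossprod(Gc) / max(1, ncol(Gc) - 1)
  egg <- eigen(gram, symmetric = TRUE)
  ev <- pmax(egg$values, 0)
  pos <- ev > 1e-12 * max(ev, 1)
  n_tex <- if (!any(pos)) 0L else {
    cum <- cumsum(ev[pos]) / sum(ev[pos])
    min(max(1L, which(cum >= variance_fraction)[1]), sum(pos))
  }
  tex_modes <- if (n_tex > 0) {
    V <- Gc %*% egg$vectors[, seq_len(n_tex), drop = FALSE]
    sweep(V, 2, sqrt(colSums(V^2)), "/")
  } else matrix(0, nrow(Gc), 0)
  model <- structure(list(
    shape_model = sm, frame = frame, tex_mean = tex_mean,
    tex_modes = tex_modes, tex_variances = ev[seq_len(n_tex)],
    update_matrix = NULL, ref_scale = ref_scale), class = "aam_model")
  # --- parameter-update regression ------------------------------------------
  np <- length(sm$variances) + 4L
  pert_list <- list(); res_list <- list()
  mags_mode <- c(0.5, 1.0)[seq_len(n_perturb)]
  mags_pose_t <- c(2, 4)[seq_len(n_perturb)]
  mags_pose_ab <- c(0.03, 0.06)[seq_len(n_perturb)]
  for (j in seq_along(eq)) {
    base_pr <- project_to_shape_space(sm, shapes[[j]])
    base_pose <- base_pr$pose
    base_b <- base_pr$b
    for (ipar in seq_len(np)) {
      mags <- if (ipar <= length(sm$variances)) {
        mags_mode * sqrt(max(sm$variances[ipar], 1e-12))
      } else if (ipar <= length(sm$variances) + 2) mags_pose_ab
      else mags_pose_t
      for (mg in mags) for (sgn in c(-1, 1)) {
        dp <- rep(0, np); dp[ipar] <- sgn * mg
        shp <- aam_shape_from_params(model, base_b + dp[seq_along(base_b)],
                                     perturb_pose(base_pose, dp, length(base_b)))
        g <- normalize_texture(sample_texture(eq[[j]], shp, frame))
        r <- aam_residual(model, g)
        pert_list[[length(pert_list) + 1]] <- dp
        res_list[[length(res_list) + 1]] <- r
      }
    }
  }
  Pm <- do.call(cbind, pert_list)        # np x N
  Rm <- do.call(cbind, res_list)         # ntex x N
  sv <- svd(Rm)
  # Rank-truncated pseudo-inverse: with more training residuals than
  # perturbation parameters the full-rank solve interpolates the training
  # pairs exactly and extrapolates wildly off-grid; keeping only the top
  # few-times-np singular directions regularizes the regression.
  keep <- which(sv$d > max(sv$d) * 1e-8)
  keep <- keep[seq_len(min(length(keep), 4L * np))]
  Rpinv <- sv$v[, keep, drop = FALSE] %*%
    diag(1 / sv$d[keep], length(keep)) %*% t(sv$u[, keep, drop = FALSE])
  model$update_matrix <- Pm %*% Rpinv    # np x ntex
  model
}

# Pose update: dp holds (ds, dr, dtx, dty) after the shape modes, where
# (ds, dr) act multiplicatively on the similarity part — ds is a relative
# scale change and dr a rotation (radians, small-angle) — so that the
# training magnitudes (3%/6% scale, 0.03/0.06 rad) are meaningful whatever
# the absolute pose scale. Translations are additive pixels.
perturb_pose <- function(pose, dp, n_modes) {
  ds <- dp[n_modes + 1]; dr <- dp[n_modes + 2]
  a <- pose["a"] * (1 + ds) - pose["b"] * dr
  b <- pose["b"] * (1 + ds) + pose["a"] * dr
  c(a = unname(a), b = unname(b),
    tx = unname(pose["tx"] + dp[n_modes + 3]),
    ty = unname(pose["ty"] + dp[n_modes + 4]))
}

aam_shape_from_params <- function(model, b, pose) {
  sm <- model$shape_model
  v <- shape_to_vec(sm$mean_shape)
  if (length(b)) v <- v + drop(sm$modes %*% b)
  pose_apply(pose, vec_to_shape(v))
}

# project-out residual: texture component outside the texture subspace
aam_residual <- function(model, g) {
  d <- g - model$tex_mean
  if (ncol(model$tex_modes))
    d <- d - model$tex_modes %*% crossprod(model$tex_modes, d)
  drop(d)
}

#' @export
print.aam_model <- function(x, ...) {
  cat(sprintf("Active Appearance Model: %d texture pixels, %d texture modes\n",
              length(x$tex_mean), ncol(x$tex_modes)))
  print(x$shape_model)
  invisible(x)
}

#' Fit an Active Appearance Model to an image
#'
#' From the initial shape, iterates: sample the texture under the current
#' shape, compute the residual against the texture model, predict a
#' parameter update through the trained update matrix, and accept the first
#' step factor in `(1, 0.5, 0.25, 0.125)` that reduces the residual norm.
#' Stops when the relative residual improvement falls below `rel_tol`, or
#' after three consecutive iterations in which no factor reduces the
#' residual (`converged = FALSE` in that case).
#'
#' @param image Grayscale matrix; histogram equalized internally.
#' @param model An `aam_model`.
#' @param init_shape Starting shape in image coordinates.
#' @param max_iter Iteration cap.
#' @param rel_tol Relative residual-improvement threshold.
#' @param roi Optional [bounding_box()]; landmarks are kept inside it
#'   (expanded by 10%).
#' @return List with `shape`, `converged`, `iterations`, `residual`.
#' @export
fit_aam <- function(image, model, init_shape, max_iter = 30, rel_tol = 1e-4,
                    roi = NULL) {
  stopifnot(inherits(model, "aam_model"))
  img <- equalize_roi(image)
  sm <- model$shape_model
  init_shape <- shape_as_matrix(init_shape)
  if (nrow(init_shape) != sm$n_points)
    stop_input("init shape has %d points, model expects %d",
               nrow(init_shape), sm$n_points)
  lim <- fit_region(init_shape, roi, nrow(image), ncol(image))
  proj <- project_to_shape_space(sm, init_shape)
  b <- proj$b; pose <- proj$pose
  shape <- aam_shape_from_params(model, b, pose)
  g <- normalize_texture(sample_texture(img, shape, model$frame))
  r <- aam_residual(model, g)
  err <- sum(r^2)
  n_modes <- length(b)
  fails <- 0; it <- 0; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1
    dp <- drop(model$update_matrix %*% r)
    improved <- FALSE
    for (f in c(1, 0.5, 0.25, 0.125)) {
      b_try <- b - f * dp[seq_len(n_modes)]
      if (n_modes) {
        limb <- 3 * sqrt(pmax(sm$variances, 1e-12))
        b_try <- pmin(pmax(b_try, -limb), limb)
      }
      pose_try <- perturb_pose(pose, -f * dp, n_modes)
      shp_try <- aam_shape_from_params(model, b_try, pose_try)
      if (any(shp_try[, 1] < lim$x1 - 1 | shp_try[, 1] > lim$x2 + 1 |
              shp_try[, 2] < lim$y1 - 1 | shp_try[, 2] > lim$y2 + 1)) next
      g_try <- normalize_texture(sample_texture(img, shp_try, model$frame))
      r_try <- aam_residual(model, g_try)
      e_try <- sum(r_try^2)
      if (e_try < err) {
        rel <- (err - e_try) / max(err, 1e-12)
        b <- b_try; pose <- pose_try; shape <- shp_try; r <- r_try
        err <- e_try
        improved <- TRUE
        if (rel < rel_tol) converged <- TRUE
        break
      }
    }
    if (!improved) {
      fails <- fails + 1
      if (fails >= 3) break
    } else {
      fails <- 0
      if (converged) break
    }
  }
  shape[, 1] <- pmin(pmax(shape[, 1], lim$x1), lim$x2)
  shape[, 2] <- pmin(pmax(shape[, 2], lim$y1), lim$y2)
  list(shape = shape, converged = converged,
       iterations = it, residual = err)
}
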