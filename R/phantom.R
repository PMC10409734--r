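# Synthetic long-leg AP radiograph phantoms with exact ground truth.
#
# A phantom is deliberately stylized: a bright femoral head disk, femur and
# tibia shafts, a proximal-tibia polygon whose upper contour is the tibial
# plateau (with the characteristic inner and outer knee points as its
# corners), a femoral condyle block above the joint gap, and a bright ankle
# block crossed by a dark horizontal tibiotalar band. Every detection stage
# keys on exactly these structures, and the generating geometry yields the
# Miniaci correction angle in closed form, so ground truth is exact.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic long-leg radiograph phantom
#'
#' Defaults describe a plausible standing AP long-leg film at desk scale:
#' 260x760 px, femoral head radius 26 px, knee width 112 px, tibiotalar band
#' 6 px high. The requested correction angle must lie in `[0, 30]` degrees
#' (clinical practice plans 4-18 degrees; the range leaves margin on both
#' sides).
#'
#' @param angle_deg Requested Miniaci correction angle (degrees, varus).
#' @param laterality `"right"` or `"left"`.
#' @param width,height Image size (pixels).
#' @param head_radius Femoral head radius (px).
#' @param knee_width Horizontal distance between the outer and inner knee
#'   points (px).
#' @param knee_y Mean y of the plateau corners (px).
#' @param plateau_tilt Vertical offset inner minus outer corner (px).
#' @param plateau_bow Downward sag of the plateau mid-edge, as a fraction of
#'   knee width.
#' @param ankle_y Row of the tibiotalar band centre (also the ground level).
#' @param talus_halfwidth Half horizontal extent of the band (px).
#' @param band_height Height of the dark band (px).
#' @param femur_halfwidth,tibia_halfwidth Shaft half-thicknesses (px).
#' @param noise `list(type = "none")`, `list(type = "gaussian", sigma = s)`
#'   (s a fraction of the dynamic range) or `list(type = "salt", density = d)`.
#' @param seed Integer seed controlling the noise realization.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(angle_deg = 12, laterality = c("right", "left"),
                         width = 260, height = 760, head_radius = 26,
                         knee_width = 112, knee_y = 430, plateau_tilt = 2,
                         plateau_bow = 0.05, ankle_y = 700,
                         talus_halfwidth = 30, band_height = 6,
                         femur_halfwidth = 16, tibia_halfwidth = 14,
                         noise = list(type = "none"), seed = 1L) {
  laterality <- match.arg(laterality)
  if (!is.finite(angle_deg) || angle_deg < 0 || angle_deg > 30)
    stop_input("requested correction angle %.2f outside [0, 30] degrees", angle_deg)
  spec <- structure(as.list(environment()), class = "phantom_spec")
  geom <- phantom_geometry(spec)   # validates in-image placement
  margin <- 5
  pts <- rbind(geom$head, geom$outer, geom$inner, geom$talus_inner,
               geom$talus_outer)
  if (any(pts[, 1] < margin) || any(pts[, 1] > width - margin) ||
      any(pts[, 2] < margin) || any(pts[, 2] > height - margin))
    stop_input("phantom structures leave the image (margin %d px)", margin)
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("Phantom spec: %s leg, %dx%d px, angle %.2f deg, noise %s, seed %d\n",
              x$laterality, x$width, x$height, x$angle_deg, x$noise$type,
              x$seed))
  invisible(x)
}

# The deterministic landmark geometry implied by a spec.
phantom_geometry <- function(spec) {
  med_dir <- if (spec$laterality == "right") 1 else -1
  cx <- spec$width / 2
  head <- pt(cx + med_dir * 10, 60 + spec$head_radius * 0.2)
  outer <- pt(cx - med_dir * spec$knee_width / 2,
              spec$knee_y - spec$plateau_tilt / 2)
  inner <- pt(cx + med_dir * spec$knee_width / 2,
              spec$knee_y + spec$plateau_tilt / 2)
  fuj <- fujisawa_point(inner, outer)   # medial = inner knee point
  hp <- hinge_point(outer, inner)
  g <- spec$ankle_y
  ank <- solve_ankle_position(head, fuj, hp, spec$angle_deg, g,
                              medial_dir = med_dir)
  t_in <- pt(ank["x"] + med_dir * spec$talus_halfwidth, g)
  t_out <- pt(ank["x"] - med_dir * spec$talus_halfwidth, g)
  list(head = head, outer = outer, inner = inner, fujisawa = fuj, hinge = hp,
       ankle = ank, talus_inner = t_in, talus_outer = t_out,
       ground_level_y = g, medial_dir = med_dir)
}

#' Place the ankle centre realizing a requested correction angle
#'
#' Inverts the Miniaci construction: given the femoral head centre, Fujisawa
#' point and hinge point, finds the point at `y = ground_level_y` such that
#' the angle at the hinge between the ray to that point and the ray to the
#' correction axis' ground intersection G equals `angle_deg`, with the ankle
#' displaced to the medial side of G (varus) for positive angles.
#'
#' @param head,fujisawa,hinge Points `(x, y)`.
#' @param angle_deg Requested angle in `[0, 30]` degrees.
#' @param ground_level_y Ground row (pixels).
#' @param medial_dir `+1` if medial is toward larger x (right leg), `-1`
#'   otherwise.
#' @return The ankle centre point.
#' @export
solve_ankle_position <- function(head, fujisawa, hinge, angle_deg,
                                 ground_level_y, medial_dir = 1) {
  if (!is.finite(angle_deg) || angle_deg < 0 || angle_deg > 30)
    stop_input("angle %.2f outside the supported [0, 30] degree range", angle_deg)
  head <- as_pt(head); fujisawa <- as_pt(fujisawa); hinge <- as_pt(hinge)
  dy <- fujisawa["y"] - head["y"]
  if (dy <= 0) stop_input("Fujisawa point must lie below the femoral head")
  t <- (ground_level_y - head["y"]) / dy
  G <- c(head["x"] + t * (fujisawa["x"] - head["x"]), ground_level_y)
  if (angle_deg == 0) return(pt(G[1], G[2]))
  v <- G - hinge
  th <- deg2rad(angle_deg)
  best <- NULL
  for (s in c(1, -1)) {
    vr <- c(cos(s * th) * v[1] - sin(s * th) * v[2],
            sin(s * th) * v[1] + cos(s * th) * v[2])
    if (vr[2] <= 0) next
    tt <- (ground_level_y - hinge["y"]) / vr[2]
    if (tt <= 0) next
    A <- hinge + tt * vr
    if (sign(A[1] - G[1]) == medial_dir) { best <- A; break }
  }
  if (is.null(best))
    stop_input("no valid medial ankle placement for angle %.2f", angle_deg)
  pt(best[1], best[2])
}

# --- knee contour template ---------------------------------------------------

# Proximal-tibia contour through the two characteristic corners. Index 1 is
# the outer (lateral) knee point; index `inner_index(n)` the inner (medial)
# one; in between lies the bowed plateau edge, after it the medial side,
# bottom and lateral side of the tibial block.
inner_index <- function(n_points) ceiling(0.55 * n_points)

#' Knee contour template through given corner points
#'
#' @param n_points Contour length: 17, 31 or 59.
#' @param outer,inner Characteristic knee points `(x, y)`.
#' @param bow Plateau mid-edge sag as a fraction of knee width.
#' @param taper Bottom-corner inward pull as a fraction of knee width.
#' @param depth Block depth below the plateau as a fraction of knee width.
#' @return `n_points` x 2 matrix of `(x, y)` contour points, with attributes
#'   `outer_index` (1) and `inner_index`.
#' @export
knee_shape_template <- function(n_points, outer, inner, bow = 0.05,
                                taper = 0.12, depth = 0.5) {
  if (!n_points %in% c(17L, 31L, 59L))
    stop_input("n_points must be one of 17, 31, 59")
  outer <- as_pt(outer); inner <- as_pt(inner)
  w <- vec_norm(inner - outer)
  if (w == 0) stop_degenerate("knee corner points coincide")
  k <- inner_index(n_points)
  # plateau edge: quadratic bow between the corners, sagging downward
  s <- seq(0, 1, length.out = k)
  top <- cbind(outer["x"] + s * (inner["x"] - outer["x"]),
               outer["y"] + s * (inner["y"] - outer["y"]) +
                 bow * w * 4 * s * (1 - s))
  # lower outline: inner corner -> inner bottom -> outer bottom -> outer corner
  dirx <- sign(inner["x"] - outer["x"])
  yb <- max(outer["y"], inner["y"]) + depth * w
  ib <- c(inner["x"] - dirx * taper * w, yb)
  ob <- c(outer["x"] + dirx * taper * w, yb)
  path <- rbind(inner, ib, ob, outer)
  seglen <- sqrt(rowSums(diff(path)^2))
  cum <- c(0, cumsum(seglen))
  m <- n_points - k                     # points after the inner corner
  tpos <- cum[length(cum)] * seq_len(m) / (m + 1)
  low <- t(vapply(tpos, function(d) {
    j <- findInterval(d, cum, rightmost.closed = TRUE)
    a <- (d - cum[j]) / seglen[j]
    (1 - a) * path[j, ] + a * path[j + 1, ]
  }, numeric(2)))
  shp <- unname(rbind(top, low))
  colnames(shp) <- c("x", "y")
  attr(shp, "outer_index") <- 1L
  attr(shp, "inner_index") <- k
  shp
}

# --- rasterization -----------------------------------------------------------

fill_polygon <- function(h, w, xs, ys) {
  out <- matrix(FALSE, h, w)
  n <- length(xs)
  x2 <- xs[c(2:n, 1)]; y2 <- ys[c(2:n, 1)]
  for (row in max(1L, floor(min(ys))):min(h, ceiling(max(ys)))) {
    yc <- row
    span <- (ys <= yc & y2 > yc) | (y2 <= yc & ys > yc)
    if (!any(span)) next
    xc <- xs[span] + (yc - ys[span]) * (x2[span] - xs[span]) / (y2[span] - ys[span])
    xc <- sort(xc)
    for (i in seq(1, length(xc) - 1, by = 2)) {
      c1 <- max(1L, ceiling(xc[i])); c2 <- min(w, floor(xc[i + 1]))
      if (c1 <= c2) out[row, c1:c2] <- TRUE
    }
  }
  out
}

draw_capsule <- function(mask, p1, p2, halfwidth) {
  h <- nrow(mask); w <- ncol(mask)
  x1 <- min(p1[1], p2[1]) - halfwidth; x2 <- max(p1[1], p2[1]) + halfwidth
  y1 <- min(p1[2], p2[2]) - halfwidth; y2 <- max(p1[2], p2[2]) + halfwidth
  xs <- max(1L, floor(x1)):min(w, ceiling(x2))
  ys <- max(1L, floor(y1)):min(h, ceiling(y2))
  if (!length(xs) || !length(ys)) return(mask)
  gx <- matrix(rep(xs, each = length(ys)), length(ys))
  gy <- matrix(rep(ys, times = length(xs)), length(ys))
  v <- p2 - p1
  L2 <- sum(v^2)
  t <- if (L2 == 0) 0 else pmin(pmax(((gx - p1[1]) * v[1] + (gy - p1[2]) * v[2]) / L2, 0), 1)
  d2 <- (gx - (p1[1] + t * v[1]))^2 + (gy - (p1[2] + t * v[2]))^2
  mask[ys, xs] <- mask[ys, xs] | (d2 <= halfwidth^2)
  mask
}

#' Render a phantom radiograph with its ground truth
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (matrix in `[0, 1]`), and `truth`: a list with
#'   `landmarks` ([leg_landmarks]), `boxes` (named ground-truth
#'   [bounding_box()] list), `correction_angle_deg`, `ground_level_y`, and
#'   `knee` (contour parameters).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- phantom_geometry(spec)
  h <- spec$height; w <- spec$width
  img <- matrix(0.05, h, w)
  put <- function(img, mask, val) { img[mask] <- val; img }

  # femoral head disk
  X <- matrix(rep(seq_len(w), each = h), h)
  Y <- matrix(rep(seq_len(h), times = w), h)
  disk <- (X - g$head["x"])^2 + (Y - g$head["y"])^2 <= spec$head_radius^2
  # shafts
  knee_top_mid <- (g$outer + g$inner) / 2
  femur <- draw_capsule(matrix(FALSE, h, w),
                        g$head + c(0, spec$head_radius * 0.6),
                        knee_top_mid - c(0, 0.42 * spec$knee_width),
                        spec$femur_halfwidth)
  tibia <- draw_capsule(matrix(FALSE, h, w),
                        knee_top_mid + c(0, 0.5 * spec$knee_width),
                        g$ankle - c(0, 22), spec$tibia_halfwidth)
  img <- put(img, femur, 0.55)
  img <- put(img, tibia, 0.55)

  # femoral condyle block above the joint gap: the tibial template reflected
  # about the (horizontal) gap line, so its lower contour runs parallel to
  # the plateau at distance `gap`
  gap <- 8
  cond <- knee_shape_template(31L, g$outer - c(0, gap), g$inner - c(0, gap),
                              bow = spec$plateau_bow, taper = 0.10, depth = 0.38)
  y0 <- mean(c(g$outer["y"], g$inner["y"])) - gap
  cond[, 2] <- 2 * y0 - cond[, 2]
  cond_poly <- fill_polygon(h, w, cond[, 1], cond[, 2])
  img <- put(img, cond_poly, 0.70)

  # proximal tibia block: plateau contour through the characteristic points
  knee <- knee_shape_template(59L, g$outer, g$inner, bow = spec$plateau_bow)
  tib_poly <- fill_polygon(h, w, knee[, 1], knee[, 2])
  img <- put(img, tib_poly, 0.85)
  img <- put(img, disk, 0.90)

  # ankle block with the dark tibiotalar band (band centre = ground level)
  ax <- g$ankle["x"]
  bx1 <- ax - spec$talus_halfwidth; bx2 <- ax + spec$talus_halfwidth
  block <- X >= bx1 & X <= bx2 & Y >= g$ground_level_y - 26 &
    Y <= g$ground_level_y + 26
  img <- put(img, block, 0.80)
  band <- X >= bx1 & X <= bx2 &
    Y >= g$ground_level_y - spec$band_height / 2 &
    Y <= g$ground_level_y + spec$band_height / 2
  img <- put(img, band, 0.05)

  img <- with_seed(spec$seed, apply_noise(img, spec$noise))

  landmarks <- leg_landmarks(
    femoral_head_center = g$head,
    medial_plateau_edge = g$inner, lateral_plateau_edge = g$outer,
    talus_inner = g$talus_inner, talus_outer = g$talus_outer,
    laterality = spec$laterality)
  boxes <- list(
    femoral_head = bounding_box("femoral_head",
      g$head["x"] - 1.3 * spec$head_radius, g$head["y"] - 1.3 * spec$head_radius,
      g$head["x"] + 1.3 * spec$head_radius, g$head["y"] + 1.3 * spec$head_radius,
      confidence = 1),
    knee = bounding_box("knee",
      min(knee[, 1]) - 0.12 * spec$knee_width, min(knee[, 2]) - 0.16 * spec$knee_width,
      max(knee[, 1]) + 0.12 * spec$knee_width, max(knee[, 2]) + 0.10 * spec$knee_width,
      confidence = 1),
    ankle = bounding_box("ankle",
      bx1 - 12, g$ground_level_y - 34, bx2 + 12, g$ground_level_y + 34,
      confidence = 1))
  boxes <- lapply(boxes, clip_box, width = w, height = h)
  list(image = img,
       truth = list(landmarks = landmarks, boxes = boxes,
                    correction_angle_deg = spec$angle_deg,
                    ground_level_y = g$ground_level_y,
                    knee = list(outer = g$outer, inner = g$inner,
                                bow = spec$plateau_bow)))
}

apply_noise <- function(img, noise) {
  type <- noise$type %||% "none"
  if (type == "none") return(img)
  if (type == "gaussian") {
    sigma <- noise$sigma %||% 0.05
    return(pmin(pmax(img + matrix(stats::rnorm(length(img), 0, sigma),
                                  nrow(img)), 0), 1))
  }
  if (type == "salt") {
    dens <- noise$density %||% 0.01
    n <- round(dens * length(img))
    if (n > 0) img[sample.int(length(img), n)] <- 1
    return(img)
  }
  stop_input("unknown noise type '%s'", type)
}

#' Ground-truth knee contour of a phantom
#'
#' @param spec A [phantom_spec()].
#' @param n_points Contour length (17, 31 or 59).
#' @return Contour matrix as from [knee_shape_template()].
#' @export
phantom_knee_shape <- function(spec, n_points = 59L) {
  g <- phantom_geometry(spec)
  knee_shape_template(n_points, g$outer, g$inner, bow = spec$plateau_bow)
}

#' Draw a family of random phantom specs
#'
#' Angles are drawn from the given distribution (by default a right-skewed
#' skew-normal resembling clinically planned correction angles, most mass in
#' 4-18 degrees), truncated to the valid `[0, 30]` range by resampling; knee
#' width, plateau tilt/bow and head radius vary mildly across specs.
#'
#' @param n Number of specs.
#' @param angle_distribution `list(type = "skew_normal", location = 6,
#'   scale = 5, shape = 4)`, `list(type = "point", value = v)`, or
#'   `list(type = "uniform", min =, max =)`.
#' @param seed Integer seed.
#' @param laterality Passed through to each spec.
#' @param noise Noise model for each spec.
#' @return List of [phantom_spec()] objects.
#' @export
sample_specs <- function(n, angle_distribution = list(type = "skew_normal",
                                                      location = 6, scale = 5,
                                                      shape = 4),
                         seed = 1L, laterality = "right",
                         noise = list(type = "none")) {
  if (n < 1) stop_input("n must be >= 1")
  with_seed(seed, {
    draw_angle <- function() {
      repeat {
        a <- switch(angle_distribution$type,
          point = angle_distribution$value,
          uniform = stats::runif(1, angle_distribution$min, angle_distribution$max),
          skew_normal = rskewnorm(1, angle_distribution$location,
                                  angle_distribution$scale,
                                  angle_distribution$shape),
          stop_input("unknown angle distribution '%s'", angle_distribution$type))
        if (a >= 0 && a <= 30) return(a)
      }
    }
    lapply(seq_len(n), function(i) {
      phantom_spec(
        angle_deg = draw_angle(), laterality = laterality,
        head_radius = round(stats::runif(1, 22, 30)),
        knee_width = round(stats::runif(1, 100, 124)),
        plateau_tilt = stats::runif(1, -3, 3),
        plateau_bow = stats::runif(1, 0.03, 0.07),
        talus_halfwidth = round(stats::runif(1, 26, 34)),
        noise = noise,
        seed = sample.int(.Machine$integer.max, 1))
    })
  })
}

#' Write a phantom fixture directory
#'
#' Renders each spec and writes `phantom_<i>.png`, a darknet box sidecar
#' `phantom_<i>.txt` and a ground-truth JSON `phantom_<i>_truth.json`.
#'
#' @param specs List of [phantom_spec()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_fixtures <- function(specs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(specs)) {
    ph <- render_phantom(specs[[i]])
    stem <- file.path(dir, sprintf("phantom_%03d", i))
    write_radiograph(ph$image, paste0(stem, ".png"))
    write_darknet_boxes(unname(ph$truth$boxes), paste0(stem, ".txt"),
                        ncol(ph$image), nrow(ph$image))
    truth <- list(
      laterality = ph$truth$landmarks$laterality,
      correction_angle_deg = ph$truth$correction_angle_deg,
      ground_level_y = ph$truth$ground_level_y)
    for (nm in LANDMARK_POINTS) {
      p <- ph$truth$landmarks[[nm]]
      truth[[nm]] <- list(x = unname(p["x"]), y = unname(p["y"]))
    }
    jsonlite::write_json(truth, paste0(stem, "_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Generate a knee-model training set from phantoms
#'
#' Renders `n` random phantoms and returns the knee region crops with the
#' ground-truth contour (in crop coordinates), ready for [train_asm()] /
#' [train_aam()].
#'
#' @param n Number of phantoms.
#' @param n_points Contour length (17, 31 or 59).
#' @param laterality Leg side.
#' @param seed Integer seed.
#' @param noise Noise model passed to [sample_specs()].
#' @return List with `images`, `shapes`, `specs`, `index_map`.
#' @export
phantom_training_set <- function(n, n_points = 59L, laterality = "right",
                                 seed = 1L, noise = list(type = "none")) {
  specs <- sample_specs(n, seed = seed, laterality = laterality, noise = noise)
  images <- list(); shapes <- list()
  for (i in seq_along(specs)) {
    ph <- render_phantom(specs[[i]])
    crop <- crop_bbox(ph$image, ph$truth$boxes$knee)
    off <- attr(crop, "offset")
    shp <- phantom_knee_shape(specs[[i]], n_points)
    shp[, 1] <- shp[, 1] - off[1]
    shp[, 2] <- shp[, 2] - off[2]
    images[[i]] <- crop
    shapes[[i]] <- shp
  }
  list(images = images, shapes = shapes, specs = specs,
       index_map = list(outer = attr(shapes[[1]], "outer_index") %||% 1L,
                        inner = inner_index(n_points)))
}
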