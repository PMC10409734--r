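#' Anatomical landmark set of one leg
#'
#' Bundles the named points the Miniaci planning method needs, in image pixel
#' coordinates (origin top-left, y downward). `laterality` is the patient's
#' side; on an anteroposterior radiograph the patient's right leg appears on
#' the image left, so for a right leg the medial plateau edge lies at larger
#' x than the lateral edge, and mirrored for a left leg.
#'
#' @param femoral_head_center,medial_plateau_edge,lateral_plateau_edge,talus_inner,talus_outer
#'   Length-2 numeric vectors `(x, y)`.
#' @param laterality `"left"` or `"right"`.
#' @param fujisawa_point,ankle_center,hinge_point Optional; derived from the
#'   other points when omitted (the usual case).
#' @param hinge_frac Hinge-point shift fractions `c(x, y)` of knee width used
#'   when `hinge_point` is derived; defaults to the population values 14% and
#'   18%.
#' @param fujisawa_frac Fraction of plateau width lateral to the medial edge
#'   at which the derived Fujisawa point sits; default 0.625.
#' @return An object of class `leg_landmarks`.
#' @export
leg_landmarks <- function(femoral_head_center, medial_plateau_edge,
                          lateral_plateau_edge, talus_inner, talus_outer,
                          laterality = c("right", "left"),
                          fujisawa_point = NULL, ankle_center = NULL,
                          hinge_point = NULL,
                          hinge_frac = c(0.14, 0.18), fujisawa_frac = 0.625) {
  laterality <- match.arg(laterality)
  lm <- list(
    femoral_head_center = as_pt(femoral_head_center, "femoral head center"),
    medial_plateau_edge = as_pt(medial_plateau_edge, "medial plateau edge"),
    lateral_plateau_edge = as_pt(lateral_plateau_edge, "lateral plateau edge"),
    talus_inner = as_pt(talus_inner, "inner talus border"),
    talus_outer = as_pt(talus_outer, "outer talus border"),
    laterality = laterality)
  lm$fujisawa_point <- if (is.null(fujisawa_point)) {
    fujisawa_point(lm$medial_plateau_edge, lm$lateral_plateau_edge,
                   frac = fujisawa_frac)
  } else as_pt(fujisawa_point, "Fujisawa point")
  lm$ankle_center <- if (is.null(ankle_center)) {
    ankle_center(lm$talus_inner, lm$talus_outer)
  } else as_pt(ankle_center, "ankle center")
  lm$hinge_point <- if (is.null(hinge_point)) {
    hinge_point(lm$lateral_plateau_edge, lm$medial_plateau_edge,
                frac_x = hinge_frac[1], frac_y = hinge_frac[2])
  } else as_pt(hinge_point, "hinge point")
  structure(lm, class = "leg_landmarks")
}

validate_leg_landmarks <- function(lm, tol = 1e-6) {
  stopifnot(inherits(lm, "leg_landmarks"))
  med <- lm$medial_plateau_edge; lat <- lm$lateral_plateau_edge
  # Fujisawa point collinear with, and inside, the plateau segment
  seg <- lat - med
  f <- lm$fujisawa_point - med
  cr <- seg[1] * f[2] - seg[2] * f[1]
  if (abs(cr) > tol * max(1, vec_norm(seg)^2))
    stop_input("fujisawa_point is not on the plateau segment")
  t <- sum(f * seg) / sum(seg^2)
  if (t < -tol || t > 1 + tol)
    stop_input("fujisawa_point lies outside the plateau segment")
  mid <- (lm$talus_inner + lm$talus_outer) / 2
  if (vec_norm(lm$ankle_center - mid) > tol * max(1, vec_norm(lm$talus_outer - lm$talus_inner)))
    stop_input("ankle_center is not the midpoint of the talus border points")
  ok <- if (lm$laterality == "right") med["x"] > lat["x"] else med["x"] < lat["x"]
  if (!isTRUE(unname(ok)))
    stop_input("medial/lateral plateau x-ordering inconsistent with laterality '%s'",
               lm$laterality)
  invisible(lm)
}

#' @export
print.leg_landmarks <- function(x, ...) {
  cat(sprintf("Leg landmarks (%s leg)\n", x$laterality))
  for (nm in c("femoral_head_center", "medial_plateau_edge", "lateral_plateau_edge",
               "fujisawa_point", "hinge_point", "talus_inner", "talus_outer",
               "ankle_center")) {
    p <- x[[nm]]
    cat(sprintf("  %-22s (%8.2f, %8.2f)\n", nm, p["x"], p["y"]))
  }
  invisible(x)
}

#' Fujisawa load-bearing target point
#'
#' The Fujisawa point sits 62.5% of the tibial plateau width lateral to the
#' medial plateau edge; the correction axis is aimed through it.
#'
#' @param medial_edge,lateral_edge Plateau edge points `(x, y)`.
#' @param frac Fraction of the medial-to-lateral segment; default 0.625.
#' @return The interpolated point.
#' @export
fujisawa_point <- function(medial_edge, lateral_edge, frac = 0.625) {
  m <- as_pt(medial_edge, "medial edge"); l <- as_pt(lateral_edge, "lateral edge")
  if (vec_norm(l - m) == 0)
    stop_degenerate("plateau edges coincide; Fujisawa point undefined")
  m + frac * (l - m)
}

#' Osteotomy hinge point
#'
#' The hinge point (centre of rotation and angulation) is placed relative to
#' the outer (lateral) knee point: shifted toward the inner point by 14% of
#' the knee width along x and downward by 18% of the knee width along y,
#' where knee width is the horizontal distance between the outer and inner
#' knee points.
#'
#' @param outer_knee,inner_knee Characteristic lateral and medial knee points.
#' @param laterality Optional `"left"`/`"right"`; checked against the x
#'   ordering of the two points when given.
#' @param frac_x,frac_y Shift fractions of knee width.
#' @return The hinge point `(x, y)`.
#' @export
hinge_point <- function(outer_knee, inner_knee, laterality = NULL,
                        frac_x = 0.14, frac_y = 0.18) {
  o <- as_pt(outer_knee, "outer knee point"); i <- as_pt(inner_knee, "inner knee point")
  w <- abs(o["x"] - i["x"])
  if (w == 0) stop_degenerate("zero knee width; hinge point undefined")
  if (!is.null(laterality)) {
    expect_inner_larger <- identical(laterality, "right")
    if ((i["x"] > o["x"]) != expect_inner_larger)
      warning("knee point x-ordering is unusual for laterality '", laterality, "'")
  }
  pt(o["x"] + sign(i["x"] - o["x"]) * frac_x * w, o["y"] + frac_y * w)
}

#' Midpoint ankle joint centre
#'
#' Reduces the two talus border points to the ankle joint centre as their
#' componentwise midpoint.
#'
#' @param inner,outer Talus border points.
#' @return Midpoint `(x, y)`.
#' @export
ankle_center <- function(inner, outer) {
  i <- as_pt(inner, "inner talus point"); o <- as_pt(outer, "outer talus point")
  if (vec_norm(i - o) == 0)
    stop_degenerate("talus border points coincide; ankle center undefined")
  (i + o) / 2
}

#' Miniaci correction angle and plan
#'
#' Extends the correction axis (femoral head centre through the Fujisawa
#' point) down to the ground level, giving the point G, and measures the
#' angle at the hinge point between the ray to the ankle joint centre and the
#' ray to G. This is the opening-wedge angle that rotates the distal limb
#' about the hinge until the ankle centre falls on the correction axis.
#'
#' The sign convention: positive angles are valgus-producing corrections,
#' i.e. the ankle centre lies medial to the correction axis (varus leg) and
#' the correction moves it laterally. The ground level defaults to the
#' y-coordinate of the ankle joint centre.
#'
#' @param landmarks A [leg_landmarks] object.
#' @param ground_level_y Pixel row of the "ground"; default the ankle centre y.
#' @return A `correction_plan` with the two axes, ground level, signed angle
#'   and hinge point.
#' @export
correction_angle <- function(landmarks, ground_level_y = NULL) {
  stopifnot(inherits(landmarks, "leg_landmarks"))
  head <- landmarks$femoral_head_center
  fuj <- landmarks$fujisawa_point
  hp <- landmarks$hinge_point
  ank <- landmarks$ankle_center
  g <- ground_level_y %||% unname(ank["y"])
  if (head["y"] >= g)
    stop_degenerate("femoral head center must lie above the ground level")
  if (vec_norm(fuj - head) == 0)
    stop_degenerate("Fujisawa point coincides with the femoral head center")
  dy <- fuj["y"] - head["y"]
  if (dy == 0)
    stop_degenerate("correction axis is horizontal; no ground intersection")
  t <- (g - head["y"]) / dy
  G <- pt(head["x"] + t * (fuj["x"] - head["x"]), g)
  u <- ank - hp; v <- G - hp
  if (vec_norm(u) == 0 || vec_norm(v) == 0)
    stop_degenerate("hinge point coincides with an axis endpoint")
  unsigned <- abs(signed_angle_deg(u, v))
  # sign: + when the ankle centre sits on the medial side of the line HP->G
  med <- landmarks$medial_plateau_edge - landmarks$lateral_plateau_edge
  perp <- u - v * sum(u * v) / sum(v^2)
  s <- sum(perp * med)
  angle <- if (s == 0 || unsigned == 0) unsigned else sign(s) * unsigned
  structure(list(
    mechanical_axis = list(femoral_head_center = head, ankle_center = ank),
    correction_axis = list(femoral_head_center = head, ground_point = G),
    ground_level_y = unname(g),
    correction_angle_deg = unname(angle),
    hinge_point = hp,
    laterality = landmarks$laterality,
    landmarks = landmarks), class = "correction_plan")
}

#' @export
print.correction_plan <- function(x, ...) {
  tag <- if (x$correction_angle_deg > 0) "varus deformity, valgus-producing opening wedge"
         else if (x$correction_angle_deg < 0) "valgus deformity"
         else "neutral"
  cat(sprintf("Miniaci correction plan (%s leg)\n", x$laterality))
  cat(sprintf("  correction angle : %.2f deg (%s)\n",
              abs(x$correction_angle_deg), tag))
  cat(sprintf("  hinge point      : (%.1f, %.1f)\n",
              x$hinge_point["x"], x$hinge_point["y"]))
  cat(sprintf("  ground level y   : %.1f\n", x$ground_level_y))
  cat(sprintf("  mechanical axis deviation from vertical: %.2f deg\n",
              mechanical_axis_angle(x$landmarks)))
  invisible(x)
}

#' Mechanical axis deviation from vertical
#'
#' Signed angle (degrees) between the mechanical axis (femoral head centre to
#' ankle joint centre) and the image vertical; an auxiliary hip-knee-ankle
#' style diagnostic. Positive when the ankle lies at larger x than the head.
#'
#' @param landmarks A [leg_landmarks] object.
#' @return Signed angle in degrees.
#' @export
mechanical_axis_angle <- function(landmarks) {
  stopifnot(inherits(landmarks, "leg_landmarks"))
  w <- landmarks$ankle_center - landmarks$femoral_head_center
  if (vec_norm(w) == 0)
    stop_degenerate("femoral head and ankle centers coincide")
  rad2deg(atan2(w[["x"]], w[["y"]]))
}
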