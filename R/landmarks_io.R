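# Reading and writing landmark records and correction plans.
#
# CSV layout: one row per leg with columns laterality and <point>_x/<point>_y
# for each named point. JSON layout: one object (or array of objects) per leg
# with laterality and named {x, y} points.

LANDMARK_POINTS <- c("femoral_head_center", "medial_plateau_edge",
                     "lateral_plateau_edge", "fujisawa_point", "talus_inner",
                     "talus_outer", "ankle_center", "hinge_point")

landmarks_from_record <- function(rec) {
  get <- function(nm) as_pt(c(rec[[paste0(nm, "_x")]] %||% rec[[nm]]$x,
                              rec[[paste0(nm, "_y")]] %||% rec[[nm]]$y), nm)
  lm <- leg_landmarks(
    femoral_head_center = get("femoral_head_center"),
    medial_plateau_edge = get("medial_plateau_edge"),
    lateral_plateau_edge = get("lateral_plateau_edge"),
    talus_inner = get("talus_inner"),
    talus_outer = get("talus_outer"),
    laterality = rec$laterality,
    fujisawa_point = tryCatch(get("fujisawa_point"), error = function(e) NULL),
    ankle_center = tryCatch(get("ankle_center"), error = function(e) NULL),
    hinge_point = tryCatch(get("hinge_point"), error = function(e) NULL))
  validate_leg_landmarks(lm)
}

landmarks_to_record <- function(lm) {
  rec <- list(laterality = lm$laterality)
  for (nm in LANDMARK_POINTS) {
    rec[[paste0(nm, "_x")]] <- unname(lm[[nm]]["x"])
    rec[[paste0(nm, "_y")]] <- unname(lm[[nm]]["y"])
  }
  rec
}

#' Read leg landmark sets from CSV or JSON
#'
#' CSV files carry one row per leg with `laterality` plus `<point>_x`,
#' `<point>_y` columns; JSON files an array of objects with named `{x, y}`
#' points. Derived points (Fujisawa, ankle centre, hinge) may be omitted and
#' are then recomputed; present ones are validated against the landmark
#' invariants.
#'
#' @param path File path (`.csv` or `.json`).
#' @return A list of [leg_landmarks] objects.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop_input("landmark file not found: %s", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    if (!is.null(recs$laterality)) recs <- list(recs)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    recs <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  }
  lapply(recs, landmarks_from_record)
}

#' Write leg landmark sets to CSV or JSON
#'
#' @param landmarks A [leg_landmarks] object or list of them.
#' @param path Output path; format chosen by extension (`.csv`/`.json`).
#' @export
write_landmarks <- function(landmarks, path) {
  if (inherits(landmarks, "leg_landmarks")) landmarks <- list(landmarks)
  recs <- lapply(landmarks, landmarks_to_record)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    out <- lapply(landmarks, function(lm) {
      o <- list(laterality = lm$laterality)
      for (nm in LANDMARK_POINTS)
        o[[nm]] <- list(x = unname(lm[[nm]]["x"]), y = unname(lm[[nm]]["y"]))
      o
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    df <- do.call(rbind, lapply(recs, function(r) as.data.frame(r)))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

plan_to_record <- function(plan) {
  p2 <- function(p) list(x = unname(p["x"]), y = unname(p["y"]))
  list(
    laterality = plan$laterality,
    correction_angle_deg = plan$correction_angle_deg,
    correction_angle_abs_deg = abs(plan$correction_angle_deg),
    deformity = if (plan$correction_angle_deg >= 0) "varus" else "valgus",
    ground_level_y = plan$ground_level_y,
    hinge_point = p2(plan$hinge_point),
    mechanical_axis = lapply(plan$mechanical_axis, p2),
    correction_axis = lapply(plan$correction_axis, p2),
    landmarks = {
      lm <- plan$landmarks
      o <- list(laterality = lm$laterality)
      for (nm in LANDMARK_POINTS) o[[nm]] <- p2(lm[[nm]])
      o
    })
}

#' Write a correction plan (or list of plans) as JSON
#'
#' @param plans A `correction_plan` or list of them.
#' @param path Output `.json` path.
#' @export
write_plan <- function(plans, path) {
  if (inherits(plans, "correction_plan")) plans <- list(plans)
  jsonlite::write_json(lapply(plans, plan_to_record), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
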