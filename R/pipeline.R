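# End-to-end orchestration: ROI boxes -> femoral head -> knee points ->
# Fujisawa point -> talus borders -> ankle centre -> hinge -> correction
# angle, per leg, with per-stage failure diagnostics.

# Config schema: every tunable with its default. Nested lists mirror the
# module structure; unknown keys are rejected at load.
hto_config_schema <- function() {
  list(
    seed = 1L,
    hough = list(c_lo = 0.5, c_hi = 1.0, vote_floor = 0.25,
                 sigma = 1.4, low = 0.1, high = 0.25),
    shape = list(n_points = 31L, model_type = "aam", k = 4L,
                 variance_fraction = 0.98, search_range = 5L,
                 asm_max_iter = 60L, asm_move_tol = 0.15,
                 aam_max_iter = 30L, aam_rel_tol = 1e-4,
                 ref_scale = 0.6, init_scale = 0.8),
    talus = list(threshold = "otsu", open_size = 3L, close_size = 7L,
                 min_area_frac = 0.001, max_tilt_deg = 15),
    geometry = list(fujisawa_frac = 0.625, hinge_frac_x = 0.14,
                    hinge_frac_y = 0.18, ground_level = "ankle"))
}

check_against_schema <- function(value, schema, path = "") {
  if (!is.list(schema)) return(invisible(TRUE))
  if (!is.list(value))
    stop_input("config section '%s' must be a mapping", path)
  extra <- setdiff(names(value), names(schema))
  if (length(extra))
    stop_input("unknown config key%s: %s",
               if (length(extra) > 1) "s" else "",
               paste0(sub("^\\.", "", paste0(path, ".", extra)), collapse = ", "))
  for (nm in names(value))
    check_against_schema(value[[nm]], schema[[nm]],
                         paste0(path, if (nzchar(path)) "." else "", nm))
  invisible(TRUE)
}

merge_config <- function(defaults, value) {
  for (nm in names(value)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(value[[nm]]))
      merge_config(defaults[[nm]], value[[nm]]) else value[[nm]]
  }
  defaults
}

#' Pipeline configuration
#'
#' Builds a validated configuration holding every pipeline tunable (Hough
#' constants, shape-model hyperparameters, talus kernel sizes, geometric
#' fractions, ground-level rule, seed). `overrides` — a nested list or a
#' YAML/JSON file path — is validated against the schema: unknown keys are
#' an error, known keys replace the defaults.
#'
#' @param overrides Nested list of settings, or a path to a YAML (`.yml`,
#'   `.yaml`) or JSON config file.
#' @return An `hto_config` (nested named list).
#' @export
hto_config <- function(overrides = list()) {
  if (is.character(overrides) && length(overrides) == 1) {
    if (!file.exists(overrides))
      stop_input("config file '%s' does not exist", overrides)
    overrides <- if (grepl("\\.ya?ml$", overrides)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop_input("the 'yaml' package is required to read YAML configs")
      yaml::read_yaml(overrides)
    } else jsonlite::read_json(overrides, simplifyVector = TRUE,
                               simplifyMatrix = FALSE)
  }
  schema <- hto_config_schema()
  if (is.null(overrides)) overrides <- list()
  check_against_schema(overrides, schema)
  cfg <- merge_config(schema, overrides)
  if (!cfg$shape$model_type %in% c("asm", "aam"))
    stop_input("shape.model_type must be 'asm' or 'aam'")
  if (!cfg$shape$n_points %in% c(17L, 31L, 59L))
    stop_input("shape.n_points must be 17, 31 or 59")
  if (!(identical(cfg$geometry$ground_level, "ankle") ||
        is.numeric(cfg$geometry$ground_level)))
    stop_input("geometry.ground_level must be \"ankle\" or a pixel row")
  structure(cfg, class = "hto_config")
}

#' @export
print.hto_config <- function(x, ...) {
  cat("HTO pipeline configuration\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

# stable hash of the configuration (for run logs): FNV-1a over the
# deparsed canonical form, reported as hex
config_hash <- function(cfg) {
  txt <- paste(deparse(unclass(cfg)), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# run one stage, recording its timing; errors propagate with stage context
run_stage <- function(stages, name, fun) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(fun(), error = function(e) e)
  elapsed <- proc.time()[["elapsed"]] - t0
  stages[[name]] <- list(seconds = elapsed,
                         ok = !inherits(res, "condition"))
  list(stages = stages, result = res)
}

plan_one_leg <- function(image, triple, laterality, model, config) {
  stages <- list()
  fail <- function(stage, cond) {
    structure(list(laterality = laterality, failed_stage = stage,
                   message = conditionMessage(cond), stages = stages),
              class = "hto_leg_failure")
  }

  # femoral head centre via circular Hough
  st <- run_stage(stages, "femoral_head", function() {
    crop <- crop_bbox(image, triple$femoral_head)
    hh <- config$hough
    femoral_head_center(crop, triple$femoral_head, c_lo = hh$c_lo,
                        c_hi = hh$c_hi, vote_floor = hh$vote_floor,
                        sigma = hh$sigma, low = hh$low, high = hh$high)
  })
  stages <- st$stages
  if (inherits(st$result, "condition")) return(fail("femoral_head", st$result))
  head_pt <- st$result$center

  # knee points via the statistical shape model
  st <- run_stage(stages, "knee_points", function() {
    crop <- crop_bbox(image, triple$knee)
    off <- attr(crop, "offset")
    sm <- if (inherits(model, "aam_model") || inherits(model, "asm_model"))
      model$shape_model else model
    local_box <- bounding_box(
      "knee", triple$knee$x_min - off[1], triple$knee$y_min - off[2],
      triple$knee$x_max - off[1], triple$knee$y_max - off[2])
    init <- init_shape_for_bbox(sm, local_box, config$shape$init_scale)
    fit <- if (inherits(model, "aam_model")) {
      fit_aam(crop, model, init, max_iter = config$shape$aam_max_iter,
              rel_tol = config$shape$aam_rel_tol, roi = local_box)
    } else if (inherits(model, "asm_model")) {
      fit_asm(crop, model, init, max_iter = config$shape$asm_max_iter,
              search_range = config$shape$search_range,
              move_tol = config$shape$asm_move_tol, roi = local_box)
    } else stop_input("model must be an asm_model or aam_model")
    kp <- knee_points(fit$shape, model)
    list(inner = pt(kp$inner["x"] + off[1], kp$inner["y"] + off[2]),
         outer = pt(kp$outer["x"] + off[1], kp$outer["y"] + off[2]),
         fit = fit)
  })
  stages <- st$stages
  if (inherits(st$result, "condition")) return(fail("knee_points", st$result))
  knee <- st$result

  # talus border points via joint-space segmentation
  st <- run_stage(stages, "talus", function() {
    crop <- crop_bbox(image, triple$ankle)
    tl <- config$talus
    jsm <- segment_joint_space(crop, threshold = tl$threshold,
                               open_size = tl$open_size,
                               close_size = tl$close_size,
                               min_area_frac = tl$min_area_frac,
                               max_tilt_deg = tl$max_tilt_deg)
    talus_border_points(jsm, laterality)
  })
  stages <- st$stages
  if (inherits(st$result, "condition")) return(fail("talus", st$result))
  talus <- st$result

  # geometry: landmarks -> correction plan
  st <- run_stage(stages, "geometry", function() {
    gm <- config$geometry
    lm <- leg_landmarks(
      femoral_head_center = head_pt,
      medial_plateau_edge = knee$inner, lateral_plateau_edge = knee$outer,
      talus_inner = talus$inner, talus_outer = talus$outer,
      laterality = laterality,
      hinge_frac = c(gm$hinge_frac_x, gm$hinge_frac_y),
      fujisawa_frac = gm$fujisawa_frac)
    gl <- if (identical(gm$ground_level, "ankle")) NULL else gm$ground_level
    correction_angle(lm, ground_level_y = gl)
  })
  stages <- st$stages
  if (inherits(st$result, "condition")) return(fail("geometry", st$result))
  plan <- st$result
  attr(plan, "stages") <- stages
  attr(plan, "knee_fit") <- knee$fit[c("converged", "iterations")]
  plan
}

#' Run the full correction-angle pipeline on a radiograph
#'
#' Executes, per leg: femoral head centre (circular Hough), knee points
#' (shape-model fit started at the knee-box centre), Fujisawa point, talus
#' border points (joint-space segmentation), ankle centre, hinge point and
#' Miniaci correction angle. Legs are processed left-to-right in image
#' order; a stage failure marks that leg as failed with the stage name and
#' never aborts the other leg.
#'
#' @param image Grayscale matrix in `[0, 1]`, or a PNG/TIFF file path.
#' @param boxes Region-of-interest input: a list of [bounding_box()], a
#'   darknet sidecar file path (labelled through `class_map`, defaulting to
#'   the [read_darknet_boxes()] mapping), or `NULL` to use the built-in
#'   [phantom_detector()].
#' @param model Trained knee model (`asm_model`/`aam_model`), or a named
#'   list with per-laterality entries `right` and `left`.
#' @param config An [hto_config()] (or overrides accepted by it).
#' @param class_map Passed to [read_darknet_boxes()] when `boxes` is a path.
#' @return An `hto_result`: list with `plans` (successful
#'   `correction_plan`s, named by laterality), `failures` (per-leg failure
#'   records), `incomplete` (legs missing boxes), `config_hash`, `timings`.
#' @export
run_hto_pipeline <- function(image, boxes = NULL, model, config = hto_config(),
                             class_map = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (!inherits(config, "hto_config")) config <- hto_config(config)
  if (is.character(image)) image <- read_radiograph(image)
  check_image(image)
  if (is.null(boxes)) {
    boxes <- phantom_detector(image)
  } else if (is.character(boxes)) {
    boxes <- if (is.null(class_map))
      read_darknet_boxes(boxes, ncol(image), nrow(image))
    else read_darknet_boxes(boxes, ncol(image), nrow(image), class_map)
  }
  labels <- vapply(boxes, function(b) b$class_label, character(1))
  if (all(table(labels) <= 1)) {
    # Single-leg image: the midline split used for two-leg radiographs is
    # meaningless here, so take the best box per class as one triple and
    # infer laterality from the medial offset of the femoral head relative
    # to the knee box (the head sits medially of the shaft axis, while the
    # ankle shifts with the deformity and is not a reliable reference).
    triple <- list()
    for (cl in ROI_CLASSES) {
      cand <- boxes[labels == cl]
      if (length(cand)) {
        conf <- vapply(cand, function(b) b$confidence, numeric(1))
        triple[[cl]] <- cand[[which.max(conf)]]
      }
    }
    lat <- if (!is.null(triple$femoral_head) && !is.null(triple$knee)) {
      if (bbox_center(triple$femoral_head)[1] >=
          bbox_center(triple$knee)[1]) "right" else "left"
    } else "unknown"
    sel <- list(incomplete = list())
    if (length(triple) == length(ROI_CLASSES)) sel[[lat]] <- triple
    else sel$incomplete[[lat]] <- setdiff(ROI_CLASSES, names(triple))
  } else {
    sel <- select_leg_boxes(boxes, ncol(image))
  }
  plans <- list(); failures <- list()
  # patient right leg appears on the image left on an AP view: process in
  # image order (left to right), i.e. right leg first
  for (lat in c("right", "left")) {
    if (is.null(sel[[lat]])) next
    mdl <- if (inherits(model, c("asm_model", "aam_model"))) model
           else model[[lat]]
    if (is.null(mdl))
      stop_input("no shape model supplied for the %s leg", lat)
    res <- plan_one_leg(image, sel[[lat]], lat, mdl, config)
    if (inherits(res, "hto_leg_failure")) failures[[lat]] <- res
    else plans[[lat]] <- res
  }
  structure(list(plans = plans, failures = failures,
                 incomplete = sel$incomplete,
                 config_hash = config_hash(config),
                 seconds = proc.time()[["elapsed"]] - t0),
            class = "hto_result")
}

#' @export
print.hto_result <- function(x, ...) {
  cat(sprintf("HTO pipeline result (config %s, %.2f s)\n",
              x$config_hash, x$seconds))
  for (lat in names(x$plans)) {
    p <- x$plans[[lat]]
    cat(sprintf("  %-5s leg: correction angle %+.2f deg\n",
                lat, p$correction_angle_deg))
  }
  for (lat in names(x$failures)) {
    f <- x$failures[[lat]]
    cat(sprintf("  %-5s leg: FAILED at stage '%s' (%s)\n",
                lat, f$failed_stage, f$message))
  }
  for (lat in names(x$incomplete))
    cat(sprintf("  %-5s leg: incomplete boxes, missing %s\n",
                lat, paste(x$incomplete[[lat]], collapse = ", ")))
  if (!length(x$plans) && !length(x$failures))
    cat("  no complete leg found\n")
  invisible(x)
}
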