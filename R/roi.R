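# Region-of-interest ingestion. Boxes come from an external detector (the
# upstream object-detection stage) as darknet-format text sidecars: one row
# per box, "class cx cy w h", all normalized to [0, 1]. A naive
# intensity-profile detector is provided so phantom images run end-to-end
# without any trained model.

ROI_CLASSES <- c("femoral_head", "knee", "ankle")

#' Construct a region-of-interest bounding box
#'
#' Corner coordinates are continuous pixels with the image's top-left corner
#' at (0, 0); pixel `j` spans `(j-1, j]`.
#'
#' @param class_label One of `"femoral_head"`, `"knee"`, `"ankle"`.
#' @param x_min,y_min,x_max,y_max Corner coordinates (pixels).
#' @param confidence Detector confidence in `[0, 1]`.
#' @return A `bounding_box` object.
#' @export
bounding_box <- function(class_label, x_min, y_min, x_max, y_max,
                         confidence = 1) {
  if (!class_label %in% ROI_CLASSES)
    stop_input("unknown box class '%s'", class_label)
  if (!(x_min < x_max && y_min < y_max))
    stop_input("degenerate bounding box [%g,%g]x[%g,%g]", x_min, x_max, y_min, y_max)
  if (confidence < 0 || confidence > 1)
    stop_input("confidence must be in [0, 1]")
  structure(list(class_label = class_label, x_min = x_min, y_min = y_min,
                 x_max = x_max, y_max = y_max, confidence = confidence),
            class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<%s box (%.1f,%.1f)-(%.1f,%.1f) conf %.2f>\n",
              x$class_label, x$x_min, x$y_min, x$x_max, x$y_max, x$confidence))
  invisible(x)
}

bbox_center <- function(b) c((b$x_min + b$x_max) / 2, (b$y_min + b$y_max) / 2)
bbox_iou <- function(a, b) {
  ix <- max(0, min(a$x_max, b$x_max) - max(a$x_min, b$x_min))
  iy <- max(0, min(a$y_max, b$y_max) - max(a$y_min, b$y_min))
  inter <- ix * iy
  union <- (a$x_max - a$x_min) * (a$y_max - a$y_min) +
    (b$x_max - b$x_min) * (b$y_max - b$y_min) - inter
  if (union <= 0) 0 else inter / union
}

clip_box <- function(b, width, height) {
  b$x_min <- max(0, b$x_min); b$y_min <- max(0, b$y_min)
  b$x_max <- min(width, b$x_max); b$y_max <- min(height, b$y_max)
  b
}

#' Crop an image to a bounding box
#'
#' @param img Image matrix.
#' @param bbox A [bounding_box()].
#' @return The cropped matrix, with attribute `offset = c(x, y)` such that
#'   full-image coordinates are crop coordinates plus the offset.
#' @export
crop_bbox <- function(img, bbox) {
  check_image(img)
  xs <- max(1L, floor(bbox$x_min) + 1L):min(ncol(img), ceiling(bbox$x_max))
  ys <- max(1L, floor(bbox$y_min) + 1L):min(nrow(img), ceiling(bbox$y_max))
  out <- img[ys, xs, drop = FALSE]
  attr(out, "offset") <- c(xs[1] - 1L, ys[1] - 1L)
  out
}

#' Read darknet-format bounding boxes
#'
#' Each row is `class cx cy w h` with centre and size normalized to the image
#' dimensions. Rows are denormalized to pixel corner coordinates, clipped to
#' the image, and mapped to class labels via `class_map`.
#'
#' @param path Sidecar text file (may be empty).
#' @param image_width,image_height Image size in pixels.
#' @param class_map Named vector or list mapping integer class ids (as
#'   character names) to labels, e.g. `c("0" = "femoral_head", ...)`.
#' @return List of [bounding_box()] objects.
#' @export
read_darknet_boxes <- function(path, image_width, image_height,
                               class_map = c("0" = "femoral_head",
                                             "1" = "knee", "2" = "ankle")) {
  if (!file.exists(path)) stop_input("box file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (!length(f) %in% c(5L, 6L))
      stop_input("malformed darknet row at line %d: '%s'", i, lines[i])
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stop_input("non-numeric field in darknet row at line %d: '%s'", i, lines[i])
    cx <- v[2]; cy <- v[3]; w <- v[4]; h <- v[5]
    if (any(c(cx, cy, w, h) < 0) || any(c(cx, cy, w, h) > 1))
      stop_input("normalized value out of [0,1] at line %d: '%s'", i, lines[i])
    key <- as.character(as.integer(v[1]))
    lbl <- if (key %in% names(class_map)) class_map[[key]] else NULL
    if (is.null(lbl) || is.na(lbl))
      stop_input("class id %d at line %d missing from class_map", as.integer(v[1]), i)
    conf <- if (length(f) == 6L) v[6] else 1
    out[[i]] <- clip_box(bounding_box(
      lbl,
      x_min = (cx - w / 2) * image_width, y_min = (cy - h / 2) * image_height,
      x_max = (cx + w / 2) * image_width, y_max = (cy + h / 2) * image_height,
      confidence = conf), image_width, image_height)
  }
  out
}

#' Write bounding boxes in the darknet dialect
#'
#' @param boxes List of [bounding_box()].
#' @param path Output text path.
#' @param image_width,image_height Image size for normalization.
#' @param class_map As in [read_darknet_boxes()]; inverted for writing.
#' @export
write_darknet_boxes <- function(boxes, path, image_width, image_height,
                                class_map = c("0" = "femoral_head",
                                              "1" = "knee", "2" = "ankle")) {
  inv <- stats::setNames(names(class_map), unlist(class_map))
  rows <- vapply(boxes, function(b) {
    sprintf("%s %.8f %.8f %.8f %.8f %.6f", inv[[b$class_label]],
            (b$x_min + b$x_max) / 2 / image_width,
            (b$y_min + b$y_max) / 2 / image_height,
            (b$x_max - b$x_min) / image_width,
            (b$y_max - b$y_min) / image_height, b$confidence)
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Partition boxes into per-leg triples
#'
#' Boxes are split into image-left and image-right halves by box-centre x
#' (image-left is the patient's right leg on an AP view); within each side
#' and class the highest-confidence box is kept. Sides missing a required
#' class are reported as incomplete.
#'
#' @param boxes List of [bounding_box()].
#' @param image_width Image width in pixels.
#' @return List with elements `right` and `left` (patient side), each either
#'   a named list `femoral_head`/`knee`/`ankle` of boxes, or `NULL`, plus
#'   `incomplete`: named list of missing classes per side.
#' @export
select_leg_boxes <- function(boxes, image_width) {
  side_of <- vapply(boxes, function(b)
    if (bbox_center(b)[1] < image_width / 2) "right" else "left", character(1))
  out <- list(right = NULL, left = NULL, incomplete = list())
  for (s in c("right", "left")) {
    bs <- boxes[side_of == s]
    if (!length(bs)) { out$incomplete[[s]] <- ROI_CLASSES; next }
    triple <- list()
    missing <- character(0)
    for (cl in ROI_CLASSES) {
      cand <- bs[vapply(bs, function(b) b$class_label == cl, logical(1))]
      if (!length(cand)) { missing <- c(missing, cl); next }
      conf <- vapply(cand, function(b) b$confidence, numeric(1))
      triple[[cl]] <- cand[[which.max(conf)]]
    }
    if (length(missing)) out$incomplete[[s]] <- missing
    else out[[s]] <- triple
  }
  out
}

# --- naive phantom detector --------------------------------------------------

# Locate head/knee/ankle boxes on phantom-style images from connected bright
# components: the head disk, femoral condyle, proximal tibia block and the
# ankle block (split in two by the dark tibiotalar band) are the only
# structures brighter than the shafts. Sufficient for the stylized phantoms;
# not intended for clinical radiographs.

component_stats <- function(mask, x0) {
  lab <- from_ebimage(EBImage::bwlabel(as_ebimage(mask)))
  ids <- setdiff(unique(as.vector(lab)), 0)
  out <- lapply(ids, function(id) {
    idx <- which(lab == id)
    if (length(idx) < 50) return(NULL)
    ys <- (idx - 1L) %% nrow(lab) + 1L
    xs <- (idx - 1L) %/% nrow(lab) + 1L
    list(area = length(idx), cy = mean(ys), cx = x0 + mean(xs),
         x1 = x0 + min(xs) - 1, x2 = x0 + max(xs),
         y1 = min(ys) - 1, y2 = max(ys))
  })
  Filter(Negate(is.null), out)
}

profile_detect_leg <- function(img, x_range) {
  sub <- img[, x_range, drop = FALSE]
  comps <- component_stats(sub > 0.6, x_range[1] - 1)
  if (length(comps) < 4) return(NULL)
  h <- nrow(img); w <- ncol(img)
  cys <- vapply(comps, `[[`, numeric(1), "cy")
  comps <- comps[order(cys)]; cys <- sort(cys)
  mk <- function(cl, x1, y1, x2, y2) {
    x1 <- max(0, x1); y1 <- max(0, y1); x2 <- min(w, x2); y2 <- min(h, y2)
    if (!(x1 < x2 && y1 < y2)) return(NULL)
    bounding_box(cl, x1, y1, x2, y2, confidence = 0.9)
  }
  # head: topmost component, expanded by the same margin as a loose box
  hd <- comps[[1]]
  r <- ((hd$x2 - hd$x1) + (hd$y2 - hd$y1)) / 4
  cx <- (hd$x1 + hd$x2) / 2; cy <- (hd$y1 + hd$y2) / 2
  head_box <- mk("femoral_head", cx - 1.3 * r, cy - 1.3 * r,
                 cx + 1.3 * r, cy + 1.3 * r)
  # ankle: the two bottom components (block halves above/below the band)
  nk <- length(comps)
  an <- comps[c(nk - 1, nk)]
  ax1 <- min(an[[1]]$x1, an[[2]]$x1); ax2 <- max(an[[1]]$x2, an[[2]]$x2)
  ay1 <- min(an[[1]]$y1, an[[2]]$y1); ay2 <- max(an[[1]]$y2, an[[2]]$y2)
  ankle_box <- mk("ankle", ax1 - 12, ay1 - 8, ax2 + 12, ay2 + 8)
  # knee: the largest remaining component is the proximal tibia block
  mid <- comps[2:(nk - 2)]
  kn <- mid[[which.max(vapply(mid, `[[`, numeric(1), "area"))]]
  kw <- kn$x2 - kn$x1
  knee_box <- mk("knee", kn$x1 - 0.12 * kw, kn$y1 - 0.16 * kw,
                 kn$x2 + 0.12 * kw, kn$y2 + 0.10 * kw)
  if (is.null(head_box) || is.null(knee_box) || is.null(ankle_box)) return(NULL)
  list(head_box, knee_box, ankle_box)
}

#' Naive detector for phantom images
#'
#' Stands in for the upstream trained detector on synthetic phantoms:
#' locates the bright femoral head disk, the knee structure and the dark
#' tibiotalar band by vertical intensity profiling, per leg half.
#'
#' @param img Phantom image matrix.
#' @return List of [bounding_box()] (three per detected leg).
#' @export
phantom_detector <- function(img) {
  check_image(img)
  w <- ncol(img)
  halves <- list(seq_len(floor(w / 2)), (floor(w / 2) + 1L):w)
  mass <- vapply(halves, function(xs) sum(img[, xs]), numeric(1))
  two_legs <- all(mass > 0.2 * max(mass)) &&
    sum(img[, max(1, floor(w / 2) - 5):min(w, floor(w / 2) + 5)]) <
      0.02 * sum(img)
  ranges <- if (two_legs) halves else list(seq_len(w))
  boxes <- list()
  for (xr in ranges) {
    legs <- profile_detect_leg(img, xr)
    if (!is.null(legs)) boxes <- c(boxes, legs)
  }
  if (!length(boxes))
    stop_detection("no leg structures found by the phantom detector")
  boxes
}
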