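# Tibiotalar joint-space segmentation. The ankle joint shows as a dark,
# nearly horizontal radiolucent band between the tibial plafond and the
# talar dome; a horizontal Sobel filter, thresholding and morphological
# cleanup isolate it, and its lateral extremes are the talus border points.

#' Segment the horizontal tibiotalar joint space
#'
#' Applies the horizontal Sobel kernel (sensitive to horizontal intensity
#' transitions), thresholds the absolute response (Otsu by default), opens
#' and closes the binary mask, removes small components, and keeps the
#' dominant band: the largest component whose principal axis lies within
#' `max_tilt_deg` of horizontal. A warning is raised when even the dominant
#' band is tilted beyond the threshold (rotated ankles defeat the method).
#'
#' @param roi_image Grayscale ankle crop (attribute `offset` honoured).
#' @param threshold `"otsu"` or a numeric cut on the normalized response.
#' @param open_size,close_size Box structuring-element sides (px).
#' @param min_area_frac Minimum component area as a fraction of ROI pixels.
#' @param max_tilt_deg Band-horizontality tolerance (degrees).
#' @return A `joint_space_mask`: list with logical `mask`, `offset`,
#'   `band_tilt_deg` and a `provenance` character vector of applied steps.
#' @export
segment_joint_space <- function(roi_image, threshold = "otsu",
                                open_size = 3L, close_size = 7L,
                                min_area_frac = 0.001, max_tilt_deg = 15) {
  check_image(roi_image)
  offset <- attr(roi_image, "offset") %||% c(0, 0)
  prov <- character(0)
  ky <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE)
  # (kernel transposed to EBImage's x-major layout)
  resp <- abs(from_ebimage(EBImage::filter2(as_ebimage(roi_image), t(ky),
                                            boundary = "replicate")))
  prov <- c(prov, "horizontal Sobel |response|")
  # absolute floor: the FFT-based convolution leaves ~1e-15 numerical noise
  # on constant regions, which the normalization below would amplify
  if (max(resp) <= 1e-8)
    stop_detection("no horizontal-edge response in the ankle region")
  resp <- resp / max(resp)
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(as_ebimage(resp), range = c(0, 1))
  } else as.numeric(threshold)
  mask <- resp > thr
  prov <- c(prov, sprintf("threshold %.4f (%s)", thr,
                          if (identical(threshold, "otsu")) "otsu" else "fixed"))
  box <- function(n) EBImage::makeBrush(max(1L, as.integer(n)), shape = "box")
  # closing first merges the paired edge responses flanking the dark band
  # into one solid component; opening then strips protrusions and specks
  mask <- from_ebimage(EBImage::closing(as_ebimage(mask), box(close_size))) > 0
  mask <- from_ebimage(EBImage::opening(as_ebimage(mask), box(open_size))) > 0
  prov <- c(prov, sprintf("closing %dx%d, opening %dx%d", close_size, close_size,
                          open_size, open_size))
  lab <- from_ebimage(EBImage::bwlabel(as_ebimage(mask)))
  tab <- tabulate(lab[lab > 0])
  min_area <- max(1, min_area_frac * length(roi_image))
  keep <- which(tab >= min_area)
  prov <- c(prov, sprintf("removed %d components < %.0f px",
                          length(tab) - length(keep), min_area))
  if (!length(keep))
    stop_detection("joint-space mask empty after filtering",
                   diagnostics = list(threshold = thr, n_components = length(tab)))
  # dominant band: largest near-horizontal component
  tilt_of <- function(id) {
    idx <- which(lab == id)
    ys <- (idx - 1L) %% nrow(lab) + 1L
    xs <- (idx - 1L) %/% nrow(lab) + 1L
    mu20 <- stats::var(xs); mu02 <- stats::var(ys)
    mu11 <- stats::cov(xs, ys)
    ang <- rad2deg(0.5 * atan2(2 * mu11, mu20 - mu02))
    abs(ang)
  }
  tilts <- vapply(keep, tilt_of, numeric(1))
  horiz <- keep[tilts <= max_tilt_deg]
  chosen <- if (length(horiz)) horiz[which.max(tab[horiz])]
            else keep[which.max(tab[keep])]
  band_tilt <- tilts[match(chosen, keep)]
  if (band_tilt > max_tilt_deg)
    warning(sprintf(
      "tibiotalar band tilted %.1f deg (> %.0f): ankle likely rotated, detection unreliable",
      band_tilt, max_tilt_deg))
  out <- lab == chosen
  prov <- c(prov, sprintf("dominant band: component %d, area %d, tilt %.1f deg",
                          chosen, tab[chosen], band_tilt))
  structure(list(mask = out, offset = offset, band_tilt_deg = band_tilt,
                 provenance = prov), class = "joint_space_mask")
}

#' @export
print.joint_space_mask <- function(x, ...) {
  cat(sprintf("Joint-space mask: %d px, tilt %.1f deg\n", sum(x$mask),
              x$band_tilt_deg))
  cat(paste0("  ", x$provenance, collapse = "\n"), "\n")
  invisible(x)
}

#' Talus border points from a joint-space mask
#'
#' The leftmost and rightmost mask columns give the band extremes; each
#' point sits at the vertical midline of the mask in its extreme column,
#' mapped to full-image coordinates through the crop offset. Assignment to
#' inner (medial) / outer (lateral) follows laterality: on an AP view the
#' medial side of a right leg is at larger x.
#'
#' @param jsm A `joint_space_mask` from [segment_joint_space()].
#' @param laterality `"right"` or `"left"`.
#' @return List with `inner` and `outer` points `(x, y)`.
#' @export
talus_border_points <- function(jsm, laterality = c("right", "left")) {
  laterality <- match.arg(laterality)
  stopifnot(inherits(jsm, "joint_space_mask"))
  mask <- jsm$mask
  if (!any(mask)) stop_detection("empty joint-space mask")
  cols <- which(colSums(mask) > 0)
  if (diff(range(cols)) + 1 < 5)
    stop_detection("joint-space band narrower than 5 px")
  pt_at <- function(col) {
    rows <- which(mask[, col])
    pt(col + jsm$offset[1], mean(range(rows)) + jsm$offset[2])
  }
  left <- pt_at(min(cols)); right <- pt_at(max(cols))
  if (laterality == "right") list(inner = right, outer = left)
  else list(inner = left, outer = right)
}
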