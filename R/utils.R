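# Internal helpers shared across modules: angle arithmetic, point plumbing,
# condition constructors, bilinear sampling.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Construct a 2-D image point
#'
#' Points live in image pixel coordinates: origin at the top-left corner,
#' x increasing rightward, y increasing downward. Pixel centres sit at
#' integer coordinates, `(1, 1)` being the centre of the top-left pixel.
#'
#' @param x,y Finite numeric scalars (pixels).
#' @return A named numeric vector `c(x =, y =)`.
#' @export
pt <- function(x, y) {
  p <- c(x = as.numeric(x), y = as.numeric(y))
  if (!all(is.finite(p))) stop_degenerate("point coordinates must be finite")
  p
}

as_pt <- function(p, what = "point") {
  if (is.list(p)) p <- unlist(p)
  if (!is.numeric(p) || length(p) != 2L || !all(is.finite(p)))
    stop_degenerate(sprintf("%s must be two finite numbers", what))
  c(x = unname(p[1]), y = unname(p[2]))
}

# condition constructors -----------------------------------------------------

stop_degenerate <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("htoplan_degenerate_geometry", "htoplan_error")))
}

stop_detection <- function(msg, ..., diagnostics = NULL) {
  stop(errorCondition(sprintf(msg, ...), diagnostics = diagnostics,
                      class = c("htoplan_detection_failure", "htoplan_error")))
}

stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("htoplan_input_error", "htoplan_error")))
}

# angles ---------------------------------------------------------------------

# Signed angle (degrees) rotating vector u onto vector v, computed with the
# two-argument arctangent of cross and dot products; stable near 0.
signed_angle_deg <- function(u, v) {
  cr <- u[1] * v[2] - u[2] * v[1]
  dt <- u[1] * v[1] + u[2] * v[2]
  rad2deg(atan2(cr, dt))
}

vec_norm <- function(v) sqrt(sum(v^2))

# images ---------------------------------------------------------------------

# Images are numeric matrices with nrow = height (y), ncol = width (x),
# intensities in [0, 1]; img[y, x]. EBImage stores transposed (x first).
as_ebimage <- function(m) EBImage::Image(t(m))
from_ebimage <- function(im) t(EBImage::imageData(im))

check_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img) || length(img) == 0L)
    stop_input("image must be a non-empty numeric matrix")
  invisible(img)
}

# Bilinear interpolation of img at continuous coordinates (x, y), vectors.
# Out-of-bounds samples are clamped to the border.
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x <- pmin(pmax(x, 1), w)
  y <- pmin(pmax(y, 1), h)
  x0 <- pmin(floor(x), w - 1L); y0 <- pmin(floor(y), h - 1L)
  if (w == 1L) x0 <- rep(1, length(x))
  if (h == 1L) y0 <- rep(1, length(y))
  fx <- x - x0; fy <- y - y0
  x1 <- pmin(x0 + 1, w); y1 <- pmin(y0 + 1, h)
  i00 <- img[cbind(y0, x0)]; i01 <- img[cbind(y0, x1)]
  i10 <- img[cbind(y1, x0)]; i11 <- img[cbind(y1, x1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) + fy * ((1 - fx) * i10 + fx * i11)
}

# Histogram equalization of a [0,1] image (global, 256 levels), as applied to
# each region-of-interest crop before shape-model work.
equalize_roi <- function(img) {
  check_image(img)
  rng <- range(img)
  if (diff(rng) <= 0) return(img)
  from_ebimage(EBImage::equalize(as_ebimage(img), range = c(0, 1), levels = 256))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
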