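# Circular Hough transform for femoral head detection.
#
# The head appears as a bright, nearly circular blob inside its region of
# interest; its border pixels (x, y) satisfy (x - a)^2 + (y - b)^2 = r^2 for
# the centre (a, b) and radius r. Each edge pixel votes for every centre at
# (rounded) distance r; the best-supported hypothesis, disambiguated by the
# gradient-direction criterion of Gerig and Klein, gives the head centre.

sobel_gradients <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- from_ebimage(EBImage::filter2(as_ebimage(img), t(kx), boundary = "replicate"))
  gy <- from_ebimage(EBImage::filter2(as_ebimage(img), kx, boundary = "replicate"))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

#' Canny-style edge map
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' gradient direction, and hysteresis thresholding. Thresholds are fractions
#' of the maximum gradient magnitude; a constant image yields an all-false
#' mask.
#'
#' @param roi_image Numeric image matrix.
#' @param sigma Smoothing standard deviation (pixels).
#' @param low,high Hysteresis thresholds as fractions of the maximum
#'   gradient magnitude.
#' @return Logical matrix of edge pixels, same shape as the input.
#' @export
edge_map <- function(roi_image, sigma = 1.4, low = 0.1, high = 0.25) {
  check_image(roi_image)
  h <- nrow(roi_image); w <- ncol(roi_image)
  # Gaussian smoothing via filter2 with replicated borders: gblur's circular
  # (FFT wrap-around) boundary would blur opposite image edges into each
  # other and fabricate border edges
  sm <- if (sigma > 0 && min(h, w) > 4) {
    rad <- max(1L, ceiling(3 * sigma))
    k1 <- exp(-(seq(-rad, rad))^2 / (2 * sigma^2))
    k <- outer(k1, k1)
    from_ebimage(EBImage::filter2(as_ebimage(roi_image), k / sum(k),
                                  boundary = "replicate"))
  } else roi_image
  g <- sobel_gradients(sm)
  mmax <- max(g$mag)
  # absolute floor: the FFT-based convolution leaves ~1e-15 numerical noise
  # on constant images, which relative thresholds would amplify
  if (mmax <= 1e-8) return(matrix(FALSE, h, w))
  # non-maximum suppression: compare each pixel to its two neighbours along
  # the quantized gradient direction
  ang <- atan2(g$gy, g$gx) %% pi
  sector <- (floor(ang / (pi / 4) + 0.5)) %% 4  # 0:E-W 1:NE-SW 2:N-S 3:NW-SE
  shift <- function(m, dy, dx) {
    out <- matrix(0, h, w)
    ys <- max(1, 1 + dy):min(h, h + dy); xs <- max(1, 1 + dx):min(w, w + dx)
    out[ys, xs] <- m[ys - dy, xs - dx]
    out
  }
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  nms <- matrix(FALSE, h, w)
  for (s in 0:3) {
    o <- offs[[s + 1]]
    n1 <- shift(g$mag, o[1], o[2]); n2 <- shift(g$mag, -o[1], -o[2])
    nms <- nms | (sector == s & g$mag >= n1 & g$mag >= n2)
  }
  strong <- nms & g$mag >= high * mmax
  weak <- nms & g$mag >= low * mmax
  if (!any(weak)) return(matrix(FALSE, h, w))
  lab <- from_ebimage(EBImage::bwlabel(as_ebimage(weak)))
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  weak & (lab %in% keep)
}

# Integer offsets (dx, dy) whose rounded Euclidean length equals r.
ring_offsets <- function(r) {
  d <- seq(-r - 1L, r + 1L)
  g <- expand.grid(dx = d, dy = d)
  keep <- round(sqrt(g$dx^2 + g$dy^2)) == r
  g[keep, , drop = FALSE]
}

#' Accumulate circle hypotheses from an edge mask
#'
#' For every candidate radius, every edge pixel votes for all centres at that
#' (rounded) distance; hypotheses are local accumulator maxima, ordered by
#' decreasing votes. The full accumulator array is returned for inspection.
#'
#' @param edges Logical edge mask.
#' @param r_min,r_max Radius range in pixels (`r_min >= 1`).
#' @param step Radius step in pixels (integer).
#' @param max_hypotheses Keep at most this many hypotheses.
#' @return A `hough_result`: list with `accumulator` (array y within x within
#'   radius), `radii`, and `hypotheses` (data frame a, b, r, votes).
#' @export
hough_accumulate <- function(edges, r_min, r_max, step = 1,
                             max_hypotheses = 32L) {
  if (!is.matrix(edges) || !is.logical(edges))
    stop_input("edges must be a logical matrix")
  if (r_min < 1 || r_max < r_min) stop_input("invalid radius range")
  h <- nrow(edges); w <- ncol(edges)
  radii <- seq(from = ceiling(r_min), to = floor(r_max), by = max(1L, round(step)))
  if (!length(radii)) stop_input("radius range contains no integer radius")
  idx <- which(edges)
  acc <- array(0L, dim = c(h, w, length(radii)))
  hyps <- NULL
  if (length(idx)) {
    ey <- (idx - 1L) %% h + 1L
    ex <- (idx - 1L) %/% h + 1L
    for (k in seq_along(radii)) {
      r <- radii[k]
      off <- ring_offsets(r)
      cx <- rep(ex, times = nrow(off)) - rep(off$dx, each = length(ex))
      cy <- rep(ey, times = nrow(off)) - rep(off$dy, each = length(ey))
      ok <- cx >= 1L & cx <= w & cy >= 1L & cy <= h
      lin <- (cx[ok] - 1L) * h + cy[ok]
      acc[, , k] <- acc[, , k] + matrix(tabulate(lin, nbins = h * w), h, w)
    }
    # local maxima per radius slice (>= all 8 neighbours, votes > 0)
    for (k in seq_along(radii)) {
      a <- acc[, , k]
      if (max(a) == 0) next
      ismax <- a > 0
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0 && dx == 0) next
        nb <- matrix(0, h, w)
        ys <- max(1, 1 + dy):min(h, h + dy); xs <- max(1, 1 + dx):min(w, w + dx)
        nb[ys, xs] <- a[ys - dy, xs - dx]
        ismax <- ismax & a >= nb
      }
      pk <- which(ismax)
      if (length(pk))
        hyps <- rbind(hyps, data.frame(
          a = (pk - 1L) %/% h + 1L, b = (pk - 1L) %% h + 1L,
          r = radii[k], votes = a[pk]))
    }
  }
  if (is.null(hyps)) {
    hyps <- data.frame(a = numeric(0), b = numeric(0), r = numeric(0),
                       votes = numeric(0))
  } else {
    hyps <- hyps[order(-hyps$votes, -hyps$r, hyps$b, hyps$a), , drop = FALSE]
    hyps <- utils::head(hyps, max_hypotheses)
    rownames(hyps) <- NULL
  }
  structure(list(accumulator = acc, radii = radii, hypotheses = hyps,
                 n_edges = length(idx)),
            class = "hough_result")
}

#' @export
print.hough_result <- function(x, ...) {
  cat(sprintf("Circular Hough transform: %d edge pixels, radii %d..%d\n",
              x$n_edges, min(x$radii), max(x$radii)))
  print(utils::head(x$hypotheses, 5))
  invisible(x)
}

# Gerig-Klein style score: mean absolute cosine between the image gradient at
# each supporting edge pixel and the radial direction to the centre.
gradient_direction_score <- function(grad, edges, a, b, r) {
  idx <- which(edges)
  if (!length(idx)) return(0)
  ey <- (idx - 1L) %% nrow(edges) + 1L
  ex <- (idx - 1L) %/% nrow(edges) + 1L
  d <- sqrt((ex - a)^2 + (ey - b)^2)
  on <- round(d) == r & d > 0
  if (!any(on)) return(0)
  ux <- (ex[on] - a) / d[on]; uy <- (ey[on] - b) / d[on]
  gx <- grad$gx[idx[on]]; gy <- grad$gy[idx[on]]
  gm <- sqrt(gx^2 + gy^2)
  ok <- gm > 0
  if (!any(ok)) return(0)
  mean(abs(gx[ok] * ux[ok] + gy[ok] * uy[ok]) / gm[ok])
}

#' Detect the femoral head centre in a region of interest
#'
#' Runs [edge_map()] and [hough_accumulate()] with the radius search limited
#' proportionally to the bounding-box size (`[c_lo, c_hi]` times half the
#' shorter box side). Among hypotheses within 5% of the maximum vote count,
#' the one whose supporting edge gradients point most directly at the centre
#' wins (ties: larger radius, then smaller y). The centre is refined to
#' sub-pixel precision by the vote-weighted centroid of the 3x3 accumulator
#' neighbourhood around the peak.
#'
#' @param roi_image Cropped grayscale matrix covering the bounding box.
#' @param bbox Optional [bounding_box()] the crop came from; used for the
#'   radius restriction and to map the centre to full-image coordinates.
#' @param c_lo,c_hi Radius restriction constants (fractions of half the
#'   shorter bounding-box side).
#' @param vote_floor Minimum peak support as a fraction of the hypothesis
#'   circumference (`2*pi*r`); below it detection fails.
#' @param sigma,low,high Passed to [edge_map()].
#' @return List with `center` (full-image `(x, y)`), `radius`, `votes`, and
#'   the `hough_result`.
#' @export
femoral_head_center <- function(roi_image, bbox = NULL, c_lo = 0.5, c_hi = 1.0,
                                vote_floor = 0.25, sigma = 1.4,
                                low = 0.1, high = 0.25) {
  check_image(roi_image)
  side <- if (is.null(bbox)) min(dim(roi_image)) else
    min(bbox$x_max - bbox$x_min, bbox$y_max - bbox$y_min)
  r_min <- max(2, c_lo * side / 2)
  r_max <- max(r_min + 1, c_hi * side / 2)
  edges <- edge_map(roi_image, sigma = sigma, low = low, high = high)
  if (!any(edges))
    stop_detection("no edges in femoral head region",
                   diagnostics = list(r_min = r_min, r_max = r_max))
  hr <- hough_accumulate(edges, r_min, r_max)
  hyp <- hr$hypotheses
  if (!nrow(hyp))
    stop_detection("no circle hypothesis found",
                   diagnostics = list(n_edges = hr$n_edges))
  cand <- hyp[hyp$votes >= 0.95 * max(hyp$votes), , drop = FALSE]
  grad <- sobel_gradients(roi_image)
  cand$score <- vapply(seq_len(nrow(cand)), function(i)
    gradient_direction_score(grad, edges, cand$a[i], cand$b[i], cand$r[i]),
    numeric(1))
  cand <- cand[order(-cand$score, -cand$r, cand$b), , drop = FALSE]
  best <- cand[1, ]
  if (best$votes < vote_floor * 2 * pi * best$r)
    stop_detection("circle support %.0f below vote floor (%.0f of %.0f needed)",
                   best$votes, vote_floor * 2 * pi * best$r, 2 * pi * best$r,
                   diagnostics = list(hypotheses = hyp))
  # sub-pixel refinement on the accumulator slice of the winning radius
  k <- match(best$r, hr$radii)
  slice <- hr$accumulator[, , k]
  ys <- max(1, best$b - 1):min(nrow(slice), best$b + 1)
  xs <- max(1, best$a - 1):min(ncol(slice), best$a + 1)
  wts <- slice[ys, xs, drop = FALSE]
  a <- sum(rep(xs, each = length(ys)) * wts) / sum(wts)
  b <- sum(rep(ys, times = length(xs)) * wts) / sum(wts)
  off <- c(0, 0)
  if (!is.null(bbox)) off <- c(floor(bbox$x_min), floor(bbox$y_min))
  list(center = pt(a + off[1], b + off[2]), radius = best$r,
       votes = best$votes, hough = hr)
}
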