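# Radiograph image IO. Images are numeric matrices, nrow = height, ncol =
# width, intensities scaled to [0, 1]; img[y, x], origin top-left.

#' Read a grayscale radiograph (PNG or TIFF)
#'
#' 8- and 16-bit images are rescaled to `[0, 1]`; colour images are reduced
#' to luminance by channel averaging.
#'
#' @param path Image path ending in `.png`, `.tif` or `.tiff`.
#' @return A numeric matrix, `nrow` = image height, `ncol` = width.
#' @export
read_radiograph <- function(path) {
  if (!file.exists(path)) stop_input("image file not found: %s", path)
  arr <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    tryCatch(png::readPNG(path), error = function(e)
      stop_input("cannot read PNG image %s: %s", path, conditionMessage(e)))
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tryCatch(tiff::readTIFF(path), error = function(e)
      stop_input("cannot read TIFF image %s: %s", path, conditionMessage(e)))
  } else stop_input("unsupported image format: %s", path)
  if (length(dim(arr)) == 3L) arr <- apply(arr[, , seq_len(min(3, dim(arr)[3])), drop = FALSE], c(1, 2), mean)
  check_image(arr)
  arr
}

#' Write a grayscale image as PNG
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param path Output `.png` path.
#' @export
write_radiograph <- function(img, path) {
  check_image(img)
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
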