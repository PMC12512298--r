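# PNG image/mask I/O. Images are held in memory as H x W x 3 integer-valued
# arrays on the 0--255 scale; masks as H x W 0/1 matrices.

#' Read an RGB image as an 8-bit array
#'
#' @param path a PNG file.
#' @return an `H x W x 3` array with integer values 0--255 (alpha dropped,
#'   grayscale replicated across channels).
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 3L))
  if (dim(a)[3] >= 4L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 1L) a <- array(a[, , 1], c(dim(a)[1:2], 3L))
  round(a * 255)
}

#' Write an 8-bit RGB array as PNG
#' @param image an `H x W x 3` array, values 0--255.
#' @param path output file.
#' @export
write_image <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read a binary mask from PNG (any nonzero value = foreground)
#' @param path a PNG file.
#' @return an `H x W` 0/1 integer matrix.
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  (a > 0) * 1L
}

#' Write a binary mask as PNG
#' @param mask an `H x W` binary matrix.
#' @param path output file.
#' @export
write_mask <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}
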