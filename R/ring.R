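# Background-ring geometry. The "ring" around a segment mask is the set of
# pixels at Chebyshev distance 1..width from the mask: morphological
# dilation by a (2*width+1)^2 square structuring element, minus the mask,
# clipped to the image frame. The square kernel is separable, so dilation
# is two 1-D passes.

#' Ring of background pixels around a segment mask
#'
#' @param mask a binary matrix (nonzero = organism) with at least one
#'   foreground pixel.
#' @param width ring width in pixels (Chebyshev distance, default 20).
#' @return a logical matrix of the same dimension marking ring pixels;
#'   always disjoint from the mask.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
#' sum(background_ring(m, 1)) # 8
#' @export
background_ring <- function(mask, width = 20L) {
  m <- as_mask(mask)
  width <- as.integer(width)
  if (width < 1L) stop("ring width must be >= 1", call. = FALSE)
  d <- dilate_1d(m, width, along = "rows")
  d <- dilate_1d(d, width, along = "cols")
  ring <- d & !m
  if (!any(ring)) {
    stop("background ring is empty: mask fills the frame", call. = FALSE)
  }
  ring
}

dilate_1d <- function(m, width, along = c("rows", "cols")) {
  along <- match.arg(along)
  if (along == "cols") return(t(dilate_1d(t(m), width, "rows")))
  n <- nrow(m)
  out <- m
  for (s in seq_len(min(width, n - 1L))) {
    out[seq_len(n - s), ] <- out[seq_len(n - s), , drop = FALSE] |
      m[(s + 1L):n, , drop = FALSE]
    out[(s + 1L):n, ] <- out[(s + 1L):n, , drop = FALSE] |
      m[seq_len(n - s), , drop = FALSE]
  }
  out
}

as_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  m <- mask > 0
  if (anyNA(m)) stop("mask must not contain NA", call. = FALSE)
  if (!any(m)) stop("mask has no foreground pixels", call. = FALSE)
  m
}
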