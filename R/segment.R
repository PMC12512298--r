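# A segment sample pairs a field image with the binary mask of the organism
# produced upstream (segmentation itself is out of scope: masks are inputs).

#' Construct a segment sample
#'
#' @param image an `H x W x 3` numeric array with channels in 0--255.
#' @param mask an `H x W` binary matrix (nonzero = organism pixel).
#' @param id identifier carried through error messages and result tables.
#' @return an object of class `segment_sample`.
#' @export
segment_sample <- function(image, mask, id = "segment") {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("image must be an H x W x 3 array", call. = FALSE)
  }
  if (!is.matrix(mask) || !all(dim(mask) == dim(image)[1:2])) {
    stop("mask must be a matrix matching the image dimensions", call. = FALSE)
  }
  m <- as_mask(mask) # errors if empty
  structure(list(image = image, mask = m, id = as.character(id)),
            class = "segment_sample")
}

#' @export
print.segment_sample <- function(x, ...) {
  cat(sprintf("<segment_sample '%s': %d x %d, %d organism pixels>\n",
              x$id, nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

masked_pixels <- function(image, mask) {
  cbind(image[, , 1][mask], image[, , 2][mask], image[, , 3][mask])
}

dominant_color_result <- function(color, proportion) {
  label <- classify_color(color)
  greenness <- if (sum(color) > 0) greenness_index(color) else NA_real_
  list(color = color, proportion = proportion,
       label = label, greenness = greenness)
}

#' Extract organism and background dominant colors for one segment
#'
#' Runs k-means dominant-color extraction on the masked organism pixels and
#' on the pixels of a background ring of Chebyshev width `ring_width` around
#' the mask, then attaches the green/brown/unclear label and the greenness
#' index of each. Segments whose organism label is `unclear` are flagged for
#' exclusion from downstream models (they are retained in output tables for
#' auditability).
#'
#' @param sample a [segment_sample()].
#' @param k cluster count for the quantizer (default 4).
#' @param ring_width background-ring width in pixels (default 20).
#' @param seed seed forwarded to [quantize_dominant_color()].
#' @return a list with elements `anole`, `background` (each with `color`,
#'   `proportion`, `label`, `greenness`) and `excluded` (logical).
#' @export
process_segment <- function(sample, k = 4, ring_width = 20L, seed = 1L) {
  stopifnot(inherits(sample, "segment_sample"))
  res <- tryCatch({
    anole <- dominant_color_result_from_pixels(
      masked_pixels(sample$image, sample$mask), k, seed)
    ring <- background_ring(sample$mask, ring_width)
    bg <- dominant_color_result_from_pixels(
      masked_pixels(sample$image, ring), k, seed)
    list(anole = anole, background = bg)
  }, error = function(e) {
    stop(sprintf("segment '%s': %s", sample$id, conditionMessage(e)),
         call. = FALSE)
  })
  res$excluded <- res$anole$label == "unclear"
  res$id <- sample$id
  res
}

dominant_color_result_from_pixels <- function(px, k, seed) {
  q <- quantize_dominant_color(px, k = k, seed = seed)
  dominant_color_result(q$color, q$proportion)
}

#' Process a list of segment samples into a color table
#'
#' @param samples a list of [segment_sample()] objects.
#' @inheritParams process_segment
#' @return a data frame with columns `id, dom_R, dom_G, dom_B, proportion,
#'   label, greenness, bg_R, bg_G, bg_B, bg_greenness, excluded_flag`.
#' @export
process_segments <- function(samples, k = 4, ring_width = 20L, seed = 1L) {
  rows <- lapply(samples, function(s) {
    r <- process_segment(s, k = k, ring_width = ring_width, seed = seed)
    data.frame(id = r$id,
               dom_R = r$anole$color[["R"]],
               dom_G = r$anole$color[["G"]],
               dom_B = r$anole$color[["B"]],
               proportion = r$anole$proportion,
               label = r$anole$label,
               greenness = r$anole$greenness,
               bg_R = r$background$color[["R"]],
               bg_G = r$background$color[["G"]],
               bg_B = r$background$color[["B"]],
               bg_greenness = r$background$greenness,
               excluded_flag = r$excluded,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
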