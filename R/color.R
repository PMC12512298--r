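# Dominant-color math on raw 8-bit RGB. No white-balance or color-constancy
# correction is applied: classification operates on the pixels as captured,
# and lighting variation is treated as irreducible noise.

#' Validate and coerce an RGB triple
#'
#' @param color numeric vector of length 3 (R, G, B), each channel in
#'   `[0, 255]`.
#' @return a named numeric vector `c(R = , G = , B = )`.
#' @keywords internal
as_rgb <- function(color) {
  if (!is.numeric(color) || length(color) != 3L || anyNA(color)) {
    stop("an RGB triple must be a numeric vector of length 3 without NA",
         call. = FALSE)
  }
  if (any(color < 0) || any(color > 255)) {
    stop("RGB channels must lie in [0, 255]", call. = FALSE)
  }
  stats::setNames(as.numeric(color), c("R", "G", "B"))
}

#' Classify a dominant color as green, brown, or unclear
#'
#' Applies the threshold rule used to label color morphs: a color is
#' \emph{green} when `G > R + 2`, \emph{brown} when `R > G + 5`, and
#' \emph{unclear} otherwise. Both inequalities are strict and cannot hold
#' simultaneously, so the three labels partition RGB space.
#'
#' @param color an RGB triple (numeric length 3, channels in 0--255).
#' @return one of `"green"`, `"brown"`, `"unclear"`.
#' @examples
#' classify_color(c(100, 110, 100)) # green
#' classify_color(c(130, 110, 100)) # brown
#' classify_color(c(100, 102, 100)) # unclear (boundary: 102 is not > 102)
#' @export
classify_color <- function(color) {
  color <- as_rgb(color)
  if (color[["G"]] > color[["R"]] + 2) {
    "green"
  } else if (color[["R"]] > color[["G"]] + 5) {
    "brown"
  } else {
    "unclear"
  }
}

#' Greenness index of a color
#'
#' The scale-free chromatic fraction `G / (R + G + B)`, used to compare an
#' organism's color with its immediate background without forcing either
#' into a discrete color category.
#'
#' @param color an RGB triple with `R + G + B > 0`.
#' @return a fraction in `[0, 1]`.
#' @examples
#' greenness_index(c(0, 255, 0))  # 1
#' greenness_index(c(85, 85, 85)) # 1/3
#' @export
greenness_index <- function(color) {
  color <- as_rgb(color)
  total <- sum(color)
  if (total <= 0) {
    stop("greenness index is undefined for (0, 0, 0)", call. = FALSE)
  }
  unname(color[["G"]] / total)
}

#' Dominant color of a pixel set by k-means quantization
#'
#' Partitions pixels into at most `k` clusters by k-means on raw channel
#' values and returns the centroid of the cluster containing the most
#' pixels, rounded to integer channels, together with that cluster's pixel
#' share. When the pixels contain fewer than `k` distinct colors the
#' clusters collapse to exact color groups and the result is the modal
#' color with its exact share.
#'
#' Determinism: the k-means restarts (10 of them) draw their initial
#' centers under `seed`, so identical inputs give identical results. Ties
#' in cluster size are broken by lexicographic (R, G, B) order of the
#' centroids.
#'
#' @param pixels an `n x 3` numeric matrix of RGB rows (or a vector of
#'   length 3 for a single pixel).
#' @param k maximum number of clusters (default 4).
#' @param seed integer seed for the k-means restarts.
#' @return `list(color = <integer RGB triple>, proportion = <share>)`.
#' @export
quantize_dominant_color <- function(pixels, k = 4, seed = 1L) {
  px <- as_pixel_matrix(pixels)
  if (nrow(px) < 1L) stop("at least one pixel is required", call. = FALSE)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)

  distinct <- unique(px)
  if (k == 1L) {
    return(list(color = round_rgb(colMeans(px)), proportion = 1.0))
  }
  if (nrow(distinct) <= k) {
    # degenerate: fewer distinct colors than clusters -> exact grouping
    key <- paste(px[, 1], px[, 2], px[, 3])
    counts <- table(key)
    dkey <- paste(distinct[, 1], distinct[, 2], distinct[, 3])
    sizes <- as.integer(counts[dkey])
    ord <- order(-sizes, distinct[, 1], distinct[, 2], distinct[, 3])
    win <- ord[1L]
    return(list(color = round_rgb(distinct[win, ]),
                proportion = sizes[win] / nrow(px)))
  }

  km <- withr::with_seed(as.integer(seed), {
    tryCatch(
      suppressWarnings(
        stats::kmeans(px, centers = k, nstart = 10L, iter.max = 100L)),
      error = function(e) {
        # initial centers sampled from duplicated rows: restart from
        # explicitly distinct colors instead
        best <- NULL
        for (i in seq_len(10L)) {
          centers <- distinct[sample.int(nrow(distinct), k), , drop = FALSE]
          fit <- suppressWarnings(
            stats::kmeans(px, centers = centers, iter.max = 100L))
          if (is.null(best) || fit$tot.withinss < best$tot.withinss) {
            best <- fit
          }
        }
        best
      })
  })
  cent <- km$centers
  ord <- order(-km$size, cent[, 1], cent[, 2], cent[, 3])
  win <- ord[1L]
  list(color = round_rgb(cent[win, ]),
       proportion = km$size[win] / nrow(px))
}

round_rgb <- function(x) {
  stats::setNames(as.integer(round(pmin(pmax(x, 0), 255))), c("R", "G", "B"))
}

as_pixel_matrix <- function(pixels) {
  if (is.null(dim(pixels))) {
    if (length(pixels) == 0L) return(matrix(numeric(0), 0L, 3L))
    pixels <- matrix(pixels, ncol = 3L, byrow = TRUE)
  }
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != 3L) stop("pixels must have 3 channels", call. = FALSE)
  storage.mode(pixels) <- "double"
  pixels
}
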