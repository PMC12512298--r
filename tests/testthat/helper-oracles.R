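# Independent oracles. Each one recomputes an expected value by a different
# route than the implementation under test.

# threshold rule, re-stated directly (vectorized)
oracle_classify <- function(R, G, B) {
  ifelse(G > R + 2, "green", ifelse(R > G + 5, "brown", "unclear"))
}

# Chebyshev ring by per-pixel stamping (implementation uses separable
# shift dilation instead)
oracle_ring <- function(mask, width) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  idx <- which(mask > 0, arr.ind = TRUE)
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c <- idx[i, 2]
    out[max(1, r - width):min(H, r + width),
        max(1, c - width):min(W, c + width)] <- TRUE
  }
  out & !(mask > 0)
}

# Bernoulli-logistic MLE by two-stage grid refinement (no IRLS)
oracle_logistic_mle <- function(x, y, half_width = 4) {
  nll <- function(b0, b1) {
    eta <- b0 + b1 * x
    -sum(y * eta - log1p(exp(eta)))
  }
  b <- c(0, 0); hw <- half_width
  for (stage in 1:7) {
    g <- expand.grid(b0 = seq(b[1] - hw, b[1] + hw, length.out = 41),
                     b1 = seq(b[2] - hw, b[2] + hw, length.out = 41))
    v <- mapply(nll, g$b0, g$b1)
    b <- as.numeric(g[which.min(v), ])
    hw <- hw / 8
  }
  b
}

# pixel matrix of a segment sample under its own mask
sample_pixels <- function(s, mask = s$mask) {
  cbind(s$image[, , 1][mask], s$image[, , 2][mask], s$image[, , 3][mask])
}

# organism label as the pipeline derives it (quantize + classify)
pipeline_label <- function(s, seed = 1L) {
  classify_color(quantize_dominant_color(sample_pixels(s), k = 4,
                                         seed = seed)$color)
}

random_rect_mask <- function(H, W, seed) {
  withr::with_seed(seed, {
    h <- sample(1:max(1, H %/% 3), 1)
    w <- sample(1:max(1, W %/% 3), 1)
    r0 <- sample(1:(H - h + 1), 1)
    c0 <- sample(1:(W - w + 1), 1)
    m <- matrix(FALSE, H, W)
    m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- TRUE
    m
  })
}
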