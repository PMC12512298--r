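# Dominant-color extraction, threshold classification, ring geometry.

test_that("classify_color partitions RGB space and matches the rule", {
  triples <- withr::with_seed(42, matrix(sample(0:255, 3000, TRUE), ncol = 3))
  got <- apply(triples, 1, classify_color)
  expect_identical(got, oracle_classify(triples[, 1], triples[, 2],
                                        triples[, 3]))
  expect_true(all(got %in% c("green", "brown", "unclear")))
  # strict-boundary cases
  expect_identical(classify_color(c(100, 110, 100)), "green")
  expect_identical(classify_color(c(130, 110, 100)), "brown")
  expect_identical(classify_color(c(100, 102, 100)), "unclear")
  expect_identical(classify_color(c(100, 103, 100)), "green")
  expect_error(classify_color(c(-1, 0, 0)), "0, 255")
})

test_that("greenness_index is G/(R+G+B) and rejects black", {
  expect_equal(greenness_index(c(0, 255, 0)), 1)
  expect_equal(greenness_index(c(85, 85, 85)), 1 / 3)
  expect_equal(greenness_index(c(50, 100, 50)), 0.5)
  expect_error(greenness_index(c(0, 0, 0)), "undefined")
})

test_that("quantize_dominant_color handles exact and degenerate inputs", {
  # single distinct color
  px <- matrix(rep(c(60, 120, 40), 1000), ncol = 3, byrow = TRUE)
  q <- quantize_dominant_color(px, k = 4, seed = 1)
  expect_equal(unname(q$color), c(60, 120, 40))
  expect_equal(q$proportion, 1.0)
  # noiseless two-color mixture: oracle = exact grouping by color equality
  px2 <- rbind(matrix(rep(c(60, 140, 50), 700), ncol = 3, byrow = TRUE),
               matrix(rep(c(120, 90, 60), 300), ncol = 3, byrow = TRUE))
  q2 <- quantize_dominant_color(px2, k = 4, seed = 1)
  expect_equal(unname(q2$color), c(60, 140, 50))
  expect_equal(q2$proportion, 0.7)
  expect_error(quantize_dominant_color(matrix(numeric(0), 0, 3)), "pixel")
})

test_that("quantize recovers the modal color of a noisy planted mixture", {
  planted <- rbind(c(60, 140, 50), c(200, 40, 40), c(40, 40, 200),
                   c(230, 230, 230))
  sizes <- c(400, 300, 200, 100)
  px <- withr::with_seed(7, {
    base <- planted[rep(1:4, sizes), ]
    pmin(pmax(base + matrix(rnorm(sum(sizes) * 3, 0, 3), ncol = 3), 0), 255)
  })
  # oracle: nearest-planted-color assignment counts
  d2 <- sapply(1:4, function(i) rowSums(sweep(px, 2, planted[i, ])^2))
  expect_equal(unname(which.max(table(factor(apply(d2, 1, which.min),
                                             1:4)))), 1L)
  q <- quantize_dominant_color(px, k = 4, seed = 3)
  expect_lt(max(abs(q$color - planted[1, ])), 5)
  expect_gt(q$proportion, 0.3)
})

test_that("quantize with k = 1 returns the rounded channel-wise mean", {
  px <- withr::with_seed(11, matrix(runif(300, 0, 255), ncol = 3))
  q <- quantize_dominant_color(px, k = 1)
  expect_equal(unname(q$color), unname(round(colMeans(px))))
  expect_equal(q$proportion, 1.0)
})

test_that("background_ring matches the brute-force Chebyshev oracle", {
  for (seed in 1:12) {
    H <- 20 + (seed %% 4) * 10
    W <- 24 + (seed %% 3) * 12
    m <- random_rect_mask(H, W, seed)
    w <- 1 + seed %% 8
    expect_identical(background_ring(m, w), oracle_ring(m, w),
                     label = sprintf("seed %d", seed))
  }
  # single pixel, width 1 -> 8 neighbours
  m1 <- matrix(FALSE, 9, 9); m1[5, 5] <- TRUE
  expect_equal(sum(background_ring(m1, 1)), 8)
  # edge-touching mask: clipping strictly reduces the count
  me <- matrix(FALSE, 30, 30); me[1:5, 1:5] <- TRUE
  expect_identical(background_ring(me, 3), oracle_ring(me, 3))
  expect_lt(sum(background_ring(me, 3)), (5 + 2 * 3)^2 - 25)
})

test_that("rings are disjoint from the mask and nest with width", {
  for (seed in 13:18) {
    m <- random_rect_mask(40, 40, seed)
    r1 <- background_ring(m, 2)
    r2 <- background_ring(m, 5)
    expect_false(any(r1 & m))
    expect_false(any(r2 & m))
    expect_true(all(r2[r1])) # r1 subset of r2
    expect_gt(sum(r2), sum(r1))
  }
  full <- matrix(TRUE, 8, 8)
  expect_error(background_ring(full, 2), "fills the frame")
})

test_that("process_segment labels organism and background correctly", {
  s <- gen_segment_image(c(60, 140, 50), c(120, 90, 60), noise_sd = 0,
                         size = 48, seed = 2, id = "zn")
  r <- process_segment(s)
  expect_identical(r$anole$label, "green")
  expect_false(r$excluded)
  expect_equal(unname(r$anole$color), c(60, 140, 50))
  expect_equal(r$background$greenness, 90 / 270)

  su <- gen_segment_image(c(100, 101, 100), c(10, 10, 10), noise_sd = 0,
                          size = 32, seed = 3, id = "uc")
  ru <- process_segment(su)
  expect_identical(ru$anole$label, "unclear")
  expect_true(ru$excluded)
})

test_that("process_segment attaches the sample id to propagated errors", {
  img <- array(100, c(32, 32, 3))
  full <- matrix(1L, 32, 32)
  s <- segment_sample(img, full, id = "badmask")
  expect_error(process_segment(s), "badmask")
})

test_that("process_segments emits the documented column layout", {
  samples <- list(
    gen_segment_image(c(60, 140, 50), c(150, 150, 120), 0, 32, 1, "a"),
    gen_segment_image(c(120, 90, 60), c(150, 150, 120), 0, 32, 2, "b"))
  tab <- process_segments(samples)
  expect_identical(names(tab),
                   c("id", "dom_R", "dom_G", "dom_B", "proportion", "label",
                     "greenness", "bg_R", "bg_G", "bg_B", "bg_greenness",
                     "excluded_flag"))
  expect_identical(tab$label, c("green", "brown"))
  expect_false(any(tab$excluded_flag))
})
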