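# Classical annotation pipelines, candidate filtering, centroid linking.

test_that("chromosome segmentation recovers a bright rectangle", {
  img <- matrix(10, 100, 100)
  img[45:56, 31:70] <- 200
  cd <- segment_chromosomes(img)
  expect_s3_class(cd, "segmentation_candidate")
  expect_equal(cd$score, 1.0)
  # mask contains the rectangle interior (up to corner rounding from the
  # boundary smoothing) and stays within its 1-px dilation
  interior <- matrix(FALSE, 100, 100); interior[47:54, 33:68] <- TRUE
  dilated <- matrix(FALSE, 100, 100); dilated[44:57, 30:71] <- TRUE
  expect_true(all(cd$mask[interior]))
  expect_true(all(dilated[cd$mask]))
  expect_gte(sum(cd$mask), 0.85 * 12 * 40)
})

test_that("objects touching the border are cleared", {
  img <- matrix(10, 100, 100)
  img[1:12, 31:70] <- 200          # touches the top border
  expect_error(segment_chromosomes(img), "empty result")

  two <- matrix(10, 100, 100)
  two[1:12, 31:70] <- 200          # border blob
  two[45:56, 31:70] <- 200         # interior blob
  cd <- segment_chromosomes(two)
  expect_true(all(which(rowSums(cd$mask) > 0) > 40))   # only interior kept
})

test_that("chromosome segmentation is invariant to intensity offsets", {
  img <- matrix(10, 80, 80)
  img[35:44, 21:60] <- 200
  a <- segment_chromosomes(img)
  b <- segment_chromosomes(img + 57)
  expect_equal(a$mask, b$mask)
})

test_that("threshold spindle pipeline joins halves and fits the ellipse", {
  # two disjoint bright half-spindle blobs join into one convex mask
  img <- matrix(30, 100, 100)
  img[ellipse_mask(100, 100, 50, 30, 10, 12)] <- 220
  img[ellipse_mask(100, 100, 50, 70, 10, 12)] <- 220
  res <- segment_spindle_threshold(img, median_size = c(3, 3))
  expect_true(res$candidate$mask[50, 50])   # the gap is inside the hull
  expect_true(res$candidate$mask[50, 30] && res$candidate$mask[50, 70])

  # solid ellipse, axes 40 x 16 px: fit within 10%
  img2 <- matrix(30, 200, 200)
  img2[ellipse_mask(200, 200, 100, 100, ry = 8, rx = 20)] <- 220
  res2 <- segment_spindle_threshold(img2, median_size = c(3, 3))
  expect_lt(abs(res2$ellipse$semi_axes[1] - 20) / 20, 0.1)
  expect_lt(abs(res2$ellipse$semi_axes[2] - 8) / 8, 0.1)

  expect_error(segment_spindle_threshold(matrix(5, 50, 50)), "degenerate")
})

test_that("threshold spindle pipeline is invariant to intensity offsets", {
  img <- matrix(30, 120, 120)
  img[ellipse_mask(120, 120, 60, 60, 10, 25)] <- 200
  a <- segment_spindle_threshold(img, median_size = c(3, 3))
  b <- segment_spindle_threshold(img + 13, median_size = c(3, 3))
  expect_equal(a$candidate$mask, b$candidate$mask)
})

test_that("inverse snake grows outward and recovers orientation", {
  ang <- 20
  img <- matrix(0, 200, 200)
  img[ellipse_mask(200, 200, 100, 100, ry = 10, rx = 25, angle_deg = ang)] <- 1
  img <- as.matrix(EBImage::gblur(img, 3))
  seed <- matrix(FALSE, 200, 200)
  seed[96:105, 96:105] <- TRUE
  res <- segment_spindle_snake(img, seed)
  expect_gte(res$candidate$area_px, sum(seed))
  expect_lt(abs(res$ellipse$angle_deg - ang), 5)

  expect_error(segment_spindle_snake(img, matrix(FALSE, 200, 200)),
               "seed error")
})

test_that("conditional filtering applies every rule and is idempotent", {
  rules <- filter_rules(min_score = 0.9, min_area_px = 50,
                        max_area_px = 5000, border_margin_px = 5)
  canvas <- c(100, 100)
  low_score <- rect_candidate(100, 100, 40, 60, 40, 60, score = 0.85)
  small <- rect_candidate(100, 100, 48, 52, 48, 52, score = 0.99)
  border <- rect_candidate(100, 100, 2, 30, 40, 60, score = 0.99)
  valid <- rect_candidate(100, 100, 40, 60, 40, 60, score = 0.95)

  kept <- conditional_filter(list(low_score, small, border, valid),
                             rules, canvas)
  expect_length(kept, 1L)
  expect_identical(kept[[1]], valid)

  expect_identical(conditional_filter(kept, rules, canvas), kept)
  expect_length(conditional_filter(list(), rules, canvas), 0L)

  # enumerated oracle over random candidates
  set.seed(444)
  cands <- lapply(1:30, function(i) {
    y0 <- sample(1:80, 1); x0 <- sample(1:80, 1)
    rect_candidate(100, 100, y0, y0 + sample(3:19, 1),
                   x0, x0 + sample(3:19, 1), score = runif(1))
  })
  kept2 <- conditional_filter(cands, rules, canvas)
  oracle <- Filter(function(cd) {
    cd$score >= 0.9 && cd$area_px >= 50 && cd$area_px <= 5000 &&
      cd$bbox["x_min"] > 5 && cd$bbox["y_min"] > 5 &&
      cd$bbox["x_max"] <= 95 && cd$bbox["y_max"] <= 95
  }, cands)
  expect_equal(length(kept2), length(oracle))
  expect_identical(kept2, oracle)
})

test_that("filter rules validate their ranges", {
  expect_error(filter_rules(min_score = 1.2), "\\[0, 1\\]")
  expect_error(filter_rules(min_area_px = 10, max_area_px = 5), "<")
  expect_error(filter_rules(border_margin_px = -1), ">= 0")
})

test_that("centroid tracking follows a moving object among distractors", {
  single <- lapply(1:5, function(t) list(rect_candidate(100, 100, 40, 50,
                                                        40, 50)))
  tr <- track_centroids(single)
  expect_equal(tr$index, rep(1L, 5))
  expect_false(any(tr$gap))

  # A selected at t = 0 stays selected (stationary A and B)
  ab <- lapply(1:4, function(t) {
    list(rect_candidate(100, 100, 10, 20, 10, 20, score = 0.9),   # A
         rect_candidate(100, 100, 70, 80, 70, 80, score = 0.8))   # B
  })
  tr2 <- track_centroids(ab)
  expect_equal(tr2$index, rep(1L, 4))

  # object moving 5 px/frame among static distractors >= 20 px away
  # (the mover carries the top score at frame 1, which seeds the track)
  moving <- lapply(1:6, function(t) {
    x0 <- 10 + 5 * (t - 1)
    list(rect_candidate(100, 100, 40, 46, x0, x0 + 6, score = 0.99),
         rect_candidate(100, 100, 80, 86, 10, 16, score = 0.90),
         rect_candidate(100, 100, 10, 16, 80, 86, score = 0.90))
  })
  tr3 <- track_centroids(moving)
  expect_equal(tr3$index, rep(1L, 6))
  # brute-force nearest-centroid check per frame
  for (t in 2:6) {
    cents <- t(vapply(moving[[t]], function(cd) cd$centroid, numeric(2)))
    d <- sqrt(rowSums(sweep(cents, 2, tr3$centroids[t - 1, ])^2))
    expect_equal(tr3$index[t], which.min(d))
  }

  # gaps carry the previous centroid forward
  gappy <- list(single[[1]], list(), single[[1]])
  tr4 <- track_centroids(gappy)
  expect_true(tr4$gap[2])
  expect_equal(tr4$index[3], 1L)

  expect_error(track_centroids(list(list(), single[[1]])), "initialization")
})
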