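# Pole refinement, six-point identity assignment, and movie tracking.

test_that("refined poles land on the mask's first/last axis crossings", {
  # filled ellipse spanning x in [10, 40] at y = 25; overshooting estimate
  mask <- ellipse_mask(50, 50, cy = 25, cx = 25, ry = 6, rx = 15)
  px <- 1
  poles <- list(c(4, 24, 0), c(44, 24, 0))   # 0-based um coords (px = 1)
  ref <- refine_poles(mask, poles, pixel_size_um = px)
  # first/last foreground pixels along y = 25 (0-based x: 10 - 1 ... )
  scan <- which(mask[25, ])
  expect_equal(ref$p1[1], scan[1] - 1, tolerance = 0.5)
  expect_equal(ref$p2[1], scan[length(scan)] - 1, tolerance = 0.5)
  expect_lte(ref$scale, 1)
  expect_true(ref$refined)

  # overshoot by 2-10 px in several constructed cases: always shrinks
  set.seed(111)
  for (rep in 1:10) {
    rx <- sample(8:18, 1)
    m <- ellipse_mask(60, 60, 30, 30, ry = 5, rx = rx)
    over <- sample(2:10, 1)
    p <- list(c(29 - rx - over, 29, 0), c(29 + rx + over, 29, 0))
    r <- refine_poles(m, p, 1)
    expect_lte(r$scale, 1)
    scan <- which(m[30, ]) - 1
    expect_equal(r$p1[1], scan[1], tolerance = 0.51)
    expect_equal(r$p2[1], scan[length(scan)], tolerance = 0.51)
  }
})

test_that("poles already on the mask boundary are returned unchanged", {
  mask <- ellipse_mask(50, 50, 25, 25, ry = 6, rx = 15)
  scan <- which(mask[25, ]) - 1
  poles <- list(c(scan[1], 24, 0), c(scan[length(scan)], 24, 0))
  ref <- refine_poles(mask, poles, 1)
  expect_false(ref$refined)
  expect_equal(ref$p1, poles[[1]], tolerance = 0.5)
  expect_equal(ref$p2, poles[[2]], tolerance = 0.5)
})

test_that("an axis that misses the mask raises a refinement error", {
  mask <- matrix(FALSE, 30, 30)
  mask[5:8, 5:8] <- TRUE
  expect_error(refine_poles(mask, list(c(0, 25, 0), c(29, 25, 0)), 1),
               "background")
  expect_error(refine_poles(matrix(FALSE, 5, 5),
                            list(c(0, 0, 0), c(4, 4, 0)), 1), "empty")
})

test_that("identity assignment corrects swapped labels per axis", {
  semi <- c(5, 2, 1)
  prev <- pose_axes(c(0, 0, 0), semi, diag(3))

  same <- assign_identities(prev, prev)
  expect_false(any(same$corrections))

  flipped <- swap_axis(prev, "length")
  fix <- assign_identities(flipped, prev)
  expect_true(fix$corrections[["length"]])
  expect_false(fix$corrections[["width"]])
  expect_equal(fix$axes$pole1, prev$pole1)

  # rotation about the height axis relabels by exhaustive minimisation
  set.seed(222)
  for (rep in 1:20) {
    R0 <- random_rotation()
    prev2 <- pose_axes(rnorm(3), semi, R0)
    cur2 <- pose_axes(prev2$centroid, semi, R0 %*% rotation_zyx(0, 0, 30))
    maybe_swapped <- if (runif(1) < 0.5) swap_axis(cur2, "length") else cur2
    got <- assign_identities(maybe_swapped, prev2)
    for (nm in list(c("pole1", "pole2"), c("width1", "width2"),
                    c("height1", "height2"))) {
      straight <- sum((got$axes[[nm[1]]] - prev2[[nm[1]]])^2) +
        sum((got$axes[[nm[2]]] - prev2[[nm[2]]])^2)
      crossed <- sum((got$axes[[nm[1]]] - prev2[[nm[2]]])^2) +
        sum((got$axes[[nm[2]]] - prev2[[nm[1]]])^2)
      expect_lte(straight, crossed)   # chosen labeling is the minimiser
    }
  }
})

test_that("a static scene tracks with zero corrections", {
  cal <- calibration(pixel_size_um = 1, z_step_um = 2, dt_min = 3)
  e <- ellipsoid3d(c(25, 25, 2), c(10, 4, 2), diag(3))
  cortex <- ellipsoid3d(c(25, 25, 2), c(20, 19, 18))
  per_frame <- replicate(21, list(spindle = e, cortex = cortex),
                         simplify = FALSE)
  tr <- track_movie(per_frame, cal)
  expect_equal(length(tr$frames), 21L)
  expect_equal(nrow(tr$corrections), 0L)
  expect_equal(nrow(tr$excluded), 0L)
  expect_equal(tr$time_min, (0:20) * 3)
})

test_that("a label swap from the 90-degree crossing is corrected once", {
  # as the long axis rotates through 90 degrees the deterministic
  # orientation sign convention flips the pole labels; tracking must
  # detect the flip at the crossing frame and nowhere else
  cal <- calibration(pixel_size_um = 1, z_step_um = 2, dt_min = 3)
  semi <- c(10, 4, 2)
  cortex <- ellipsoid3d(c(25, 25, 2), c(20, 19, 18))
  per_frame <- lapply(1:21, function(t) {
    R <- rotation_zyx(0, 0, 83.5 + t)   # crosses 90 between t = 6 and t = 7
    list(spindle = ellipsoid3d(c(25, 25, 2), semi, R), cortex = cortex)
  })
  tr <- track_movie(per_frame, cal)
  expect_equal(length(tr$frames), 21L)
  len_corr <- tr$corrections[tr$corrections$axis == "length", ]
  expect_equal(len_corr$frame, 7L)
  # after correction, pole identities are consistent frame to frame
  for (k in 2:21) {
    d_same <- sum((tr$frames[[k]]$pole1 - tr$frames[[k - 1]]$pole1)^2)
    d_cross <- sum((tr$frames[[k]]$pole1 - tr$frames[[k - 1]]$pole2)^2)
    expect_lte(d_same, d_cross)
  }
})

test_that("tracking minimises total per-axis displacement (brute force)", {
  set.seed(333)
  semi <- c(5, 2, 1)
  for (rep in 1:5) {
    n <- 8
    Rs <- list(random_rotation())
    for (k in 2:n) {
      Rs[[k]] <- Rs[[k - 1]] %*% rotation_zyx(rnorm(1, 0, 4), rnorm(1, 0, 4),
                                              rnorm(1, 0, 8))
    }
    frames <- lapply(Rs, function(R) pose_axes(c(0, 0, 0), semi, R))
    # randomly corrupt labels, then track
    corrupted <- lapply(frames, function(f) {
      for (ax in c("length", "width", "height")) {
        if (runif(1) < 0.5) f <- swap_axis(f, ax)
      }
      f
    })
    tracked <- list(corrupted[[1]])
    for (k in 2:n) {
      tracked[[k]] <- assign_identities(corrupted[[k]], tracked[[k - 1]])$axes
    }
    # brute force: all 2^(n-1) labelings per axis, minimise summed distance
    for (nm in list(c("pole1", "pole2"), c("width1", "width2"),
                    c("height1", "height2"))) {
      pts1 <- t(vapply(corrupted, function(f) f[[nm[1]]], numeric(3)))
      pts2 <- t(vapply(corrupted, function(f) f[[nm[2]]], numeric(3)))
      best <- Inf
      for (code in 0:(2^(n - 1) - 1)) {
        flips <- c(FALSE, bitwAnd(code, 2^(0:(n - 2))) > 0)
        total <- 0
        prev_a <- pts1[1, ]; prev_b <- pts2[1, ]
        for (k in 2:n) {
          ka <- if (flips[k]) pts2[k, ] else pts1[k, ]
          kb <- if (flips[k]) pts1[k, ] else pts2[k, ]
          total <- total + sum((ka - prev_a)^2) + sum((kb - prev_b)^2)
          prev_a <- ka; prev_b <- kb
        }
        best <- min(best, total)
      }
      got <- 0
      for (k in 2:n) {
        got <- got + sum((tracked[[k]][[nm[1]]] - tracked[[k - 1]][[nm[1]]])^2) +
          sum((tracked[[k]][[nm[2]]] - tracked[[k - 1]][[nm[2]]])^2)
      }
      expect_equal(got, best, tolerance = 1e-9)
    }
  }
})

test_that("tracking output is invariant under a global rigid transform", {
  cal <- calibration(pixel_size_um = 1, z_step_um = 2, dt_min = 3)
  semi <- c(10, 4, 2)
  cortex0 <- c(25, 25, 2)
  per_frame <- lapply(1:6, function(t) {
    R <- rotation_zyx(3 * t, 0, 5 * t)
    list(spindle = ellipsoid3d(cortex0 + c(0.1 * t, 0, 0), semi, R),
         cortex = ellipsoid3d(cortex0, c(20, 19, 18)))
  })
  Q <- random_rotation()
  shift <- c(3, -2, 1)
  moved <- lapply(per_frame, function(fr) {
    list(spindle = ellipsoid3d(drop(Q %*% fr$spindle$center) + shift,
                               fr$spindle$semi_axes,
                               Q %*% fr$spindle$orientation),
         cortex = ellipsoid3d(drop(Q %*% fr$cortex$center) + shift,
                              fr$cortex$semi_axes,
                              Q %*% fr$cortex$orientation))
  })
  t1 <- track_movie(per_frame, cal)
  t2 <- track_movie(moved, cal)
  expect_equal(t1$corrections, t2$corrections)
  expect_equal(t1$distances$d1 + t1$distances$d2,
               t2$distances$d1 + t2$distances$d2, tolerance = 1e-9)
  l1 <- vapply(t1$frames, function(f) f$length_um, 0)
  l2 <- vapply(t2$frames, function(f) f$length_um, 0)
  expect_equal(l1, l2, tolerance = 1e-9)
})

test_that("frames with poles outside the cortex are excluded and logged", {
  cal <- calibration(pixel_size_um = 1, z_step_um = 2, dt_min = 3)
  cortex <- ellipsoid3d(c(25, 25, 2), c(12, 11, 10))
  ok <- ellipsoid3d(c(25, 25, 2), c(10, 4, 2), diag(3))
  bad <- ellipsoid3d(c(35, 25, 2), c(10, 4, 2), diag(3))  # pole at x = 45
  tr <- track_movie(list(list(spindle = ok, cortex = cortex),
                         list(spindle = bad, cortex = cortex),
                         list(spindle = ok, cortex = cortex)), cal)
  expect_equal(tr$frame_index, c(1L, 3L))
  expect_equal(tr$excluded$frame, 2L)
  expect_match(tr$excluded$reason, "containment|outside")
  expect_error(track_movie(list(), cal), "at least one")
})
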