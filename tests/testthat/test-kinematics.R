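# Euler-angle extraction and displacement decomposition.

test_that("frame rotation recovers the applied rotation", {
  semi <- c(5, 2, 1)
  base <- pose_axes(c(1, 2, 3), semi, diag(3))
  expect_equal(frame_rotation(base, base), diag(3), tolerance = 1e-12)

  R30 <- rotation_zyx(0, 0, 30)
  cur <- pose_axes(c(1, 2, 3), semi, R30)
  expect_equal(frame_rotation(base, cur), R30, tolerance = 1e-9)

  set.seed(606)
  for (rep in 1:20) {
    Q0 <- random_rotation()
    Q <- random_rotation()
    prev <- pose_axes(rnorm(3), semi, Q0)
    cur <- pose_axes(rnorm(3), semi, Q %*% Q0)
    expect_equal(frame_rotation(prev, cur), Q, tolerance = 1e-9)
  }
})

test_that("euler angles round-trip through the ZYX composition", {
  expect_equal(unlist(euler_angles(diag(3))[1:3]),
               c(alpha_deg = 0, beta_deg = 0, gamma_deg = 0))
  a30 <- euler_angles(rotation_zyx(0, 0, 30))
  expect_equal(c(a30$alpha_deg, a30$beta_deg, a30$gamma_deg), c(0, 0, 30),
               tolerance = 1e-12)

  set.seed(707)
  worst <- 0
  for (rep in 1:1000) {
    ang <- c(runif(1, -179, 179), runif(1, -85, 85), runif(1, -179, 179))
    R <- rotation_zyx(ang[1], ang[2], ang[3])
    e <- euler_angles(R)
    R2 <- rotation_zyx(e$alpha_deg, e$beta_deg, e$gamma_deg)
    worst <- max(worst, max(abs(R2 - R)))
    expect_equal(c(e$alpha_deg, e$beta_deg, e$gamma_deg), ang,
                 tolerance = 1e-9)
  }
  expect_lt(worst, 1e-9)
})

test_that("gimbal lock is flagged and still recomposes", {
  R <- rotation_zyx(25, 90, 40)
  e <- euler_angles(R)
  expect_true(e$gimbal_lock)
  expect_equal(abs(e$beta_deg), 90)
  expect_equal(e$gamma_deg, 0)
  expect_equal(rotation_zyx(e$alpha_deg, e$beta_deg, e$gamma_deg), R,
               tolerance = 1e-9)
})

test_that("pure axis rotations yield exactly one nonzero angle", {
  semi <- c(5, 2, 1)
  base <- pose_axes(c(0, 0, 0), semi, diag(3))
  for (k in 1:3) {
    ang <- c(0, 0, 0)
    ang[k] <- 17
    cur <- pose_axes(c(0, 0, 0), semi, rotation_zyx(ang[1], ang[2], ang[3]))
    e <- euler_angles(frame_rotation(base, cur))
    got <- c(e$alpha_deg, e$beta_deg, e$gamma_deg)
    expect_equal(got, ang, tolerance = 1e-9)
  }
})

test_that("displacement decomposes along the spindle frame", {
  semi <- c(5, 2, 1)
  R <- random_rotation()
  prev <- pose_axes(c(0, 0, 0), semi, R)

  cur <- pose_axes(R[, 1] * 0.8, semi, R)     # move along the length axis
  d <- decompose_displacement(prev, cur)
  expect_equal(c(d$f_lg, d$f_eq, d$f_ax), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(d$delta_lg, 0.8, tolerance = 1e-12)

  cur2 <- pose_axes(R[, 1] + R[, 2], semi, R)
  d2 <- decompose_displacement(prev, cur2)
  expect_equal(c(d2$f_lg, d2$f_eq, d2$f_ax), c(1 / sqrt(2), 1 / sqrt(2), 0),
               tolerance = 1e-12)

  # change-of-basis oracle on random displacements
  set.seed(808)
  for (rep in 1:20) {
    delta <- rnorm(3)
    cur3 <- pose_axes(delta, semi, R)
    d3 <- decompose_displacement(prev, cur3)
    oracle <- solve(cbind(R[, 1], R[, 2], R[, 3]), delta)
    expect_equal(c(d3$delta_lg, d3$delta_eq, d3$delta_ax), unname(oracle),
                 tolerance = 1e-12)
    expect_equal(d3$f_lg^2 + d3$f_eq^2 + d3$f_ax^2, 1, tolerance = 1e-9)
  }

  z <- decompose_displacement(prev, prev)
  expect_true(z$zero_motion)
  expect_equal(c(z$f_lg, z$f_eq, z$f_ax), c(0, 0, 0))
})

test_that("displacement vectors telescope across a track", {
  set.seed(909)
  semi <- c(5, 2, 1)
  R <- diag(3)
  centroids <- rbind(c(0, 0, 0), matrix(rnorm(15, sd = 0.3), 5, 3))
  centroids <- apply(centroids, 2, cumsum)
  frames <- lapply(seq_len(6), function(i) pose_axes(centroids[i, ], semi, R))
  total <- Reduce(`+`, lapply(2:6, function(i) {
    d <- decompose_displacement(frames[[i - 1]], frames[[i]])
    c(d$delta_lg, d$delta_eq, d$delta_ax)
  }))
  expect_equal(total, centroids[6, ] - centroids[1, ], tolerance = 1e-9)
})

test_that("track summaries report medians and nearest-rank ECDF values", {
  expect_equal(spindletrack:::ecdf_quantile(c(1, 2, 3, 4), 0.75), 3)
  expect_equal(spindletrack:::ecdf_quantile(c(4, 1, 3, 2), 0.5), 2)
  expect_equal(spindletrack:::ecdf_quantile(5, 0.75), 5)

  semi <- c(5, 2, 1)
  static <- replicate(4, pose_axes(c(1, 1, 1), semi, diag(3)),
                      simplify = FALSE)
  tr <- structure(list(frames = static, dt_min = 3), class = "spindle_track")
  s <- summarize_track(tr)
  expect_equal(unname(s$median_abs_angles_deg), c(0, 0, 0))

  # scripted 5 deg/frame rotation about the height (z) axis
  frames <- lapply(0:5, function(k) {
    pose_axes(c(0, 0, 0), semi, rotation_zyx(0, 0, 5 * k))
  })
  tr2 <- structure(list(frames = frames, dt_min = 3), class = "spindle_track")
  s2 <- summarize_track(tr2)
  expect_equal(unname(s2$median_abs_angles_deg),
               c(0, 0, 5), tolerance = 1e-9)
  expect_equal(unname(s2$cumulative_angles_deg$gamma_deg),
               seq(5, 25, by = 5), tolerance = 1e-9)

  expect_error(summarize_track(structure(list(frames = static[1]),
                                         class = "spindle_track")),
               "at least 2")
})
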