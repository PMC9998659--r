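# TIFF movie IO, padding preprocessor, track CSV round trips.

test_that("movie read/write round-trips bit-exactly for integer data", {
  cal <- calibration(0.06887, 2, 3)
  set.seed(666)
  arr <- array(sample(0:65535, 7 * 3 * 16 * 16, replace = TRUE),
               c(7, 3, 16, 16))
  mov <- movie(list(spindle = arr), cal)
  path <- tempfile(fileext = ".tif")
  write_movie(mov, path, bits = 16L)
  back <- read_movie(path, cal, n_slices = 3, channel_names = "spindle")
  expect_equal(dim(back$channels$spindle), c(7, 3, 16, 16))
  expect_identical(back$channels$spindle, arr + 0)   # numeric compare
  unlink(path)
})

test_that("page counts are validated against the declared geometry", {
  cal <- calibration()
  path <- tempfile(fileext = ".tif")
  # 63 pages at Z = 3 -> 21 frames
  pages <- replicate(63, matrix(runif(64), 8, 8), simplify = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  mov <- read_movie(path, cal, n_slices = 3)
  expect_equal(dim(mov$channels[[1]])[1:2], c(21L, 3L))

  # single page, Z = 1 -> identity
  one <- matrix((0:63) / 65535, 8, 8)
  tiff::writeTIFF(one, path, bits.per.sample = 16L)
  m1 <- read_movie(path, cal, n_slices = 1)
  expect_equal(dim(m1$channels[[1]]), c(1L, 1L, 8L, 8L))
  expect_equal(m1$channels[[1]][1, 1, , ], round(one * 65535))

  # 10 pages is not divisible by Z = 3
  tiff::writeTIFF(replicate(10, one, simplify = FALSE), path,
                  bits.per.sample = 16L)
  expect_error(read_movie(path, cal, n_slices = 3), "dimension error")
  expect_error(read_movie(tempfile(), cal, 3), "not found")
  unlink(path)
})

test_that("padding centers the image and tiles the dimmest patch", {
  const <- matrix(7, 20, 20)
  out <- pad_image(const, c(50, 50), c(5, 5))
  expect_equal(dim(out), c(50, 50))
  expect_true(all(out == 7))

  img <- matrix(runif(400), 20, 20)
  expect_identical(pad_image(img, c(20, 20), c(5, 5)), img)
  expect_error(pad_image(img, c(10, 30), c(5, 5)), "size error")

  # bright corner: padded pixels never exceed the dimmest patch's maximum
  set.seed(777)
  img2 <- matrix(runif(100 * 100), 100, 100)
  img2[1:20, 1:20] <- img2[1:20, 1:20] + 5
  out2 <- pad_image(img2, c(512, 512), c(10, 10))
  # brute-force enumeration of all 10x10 patch sums
  sums <- matrix(Inf, 91, 91)
  for (r in 1:91) for (cc in 1:91) {
    sums[r, cc] <- sum(img2[r:(r + 9), cc:(cc + 9)])
  }
  best <- which(sums == min(sums), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2])[1], ]
  patch <- img2[best[1]:(best[1] + 9), best[2]:(best[2] + 9)]
  pad_mask <- matrix(TRUE, 512, 512)
  pad_mask[207:306, 207:306] <- FALSE    # centered original region
  expect_lte(max(out2[pad_mask]), max(patch))
  # original occupies the centered region unchanged
  expect_identical(out2[207:306, 207:306], img2)
  # histogram restricted to the original region equals the input histogram
  expect_identical(sort(as.vector(out2[207:306, 207:306])),
                   sort(as.vector(img2)))
})

test_that("track CSVs round-trip to 1e-9 and reject empty tracks", {
  cal <- calibration(pixel_size_um = 1, z_step_um = 2, dt_min = 3)
  cortex <- ellipsoid3d(c(25, 25, 2), c(20, 19, 18))
  per_frame <- lapply(1:21, function(t) {
    list(spindle = ellipsoid3d(c(25 + 0.05 * t, 25, 2), c(10, 4, 2),
                               rotation_zyx(0, 0, 2 * t)),
         cortex = cortex)
  })
  tr <- track_movie(per_frame, cal)
  path <- tempfile(fileext = ".csv")
  write_tracks(tr, path)
  lines <- readLines(path)
  expect_length(lines, 22L)                       # header + 21 rows
  df <- read_tracks(path)
  expect_equal(nrow(df), 21L)
  p1 <- t(vapply(tr$frames, function(f) f$pole1, numeric(3)))
  expect_equal(unname(cbind(df$pole1_x, df$pole1_y, df$pole1_z)), unname(p1),
               tolerance = 1e-12)
  expect_equal(df$pole1_cortex_dist, tr$distances$d1, tolerance = 1e-12)
  expect_true(all(is.na(df$alpha[1])))
  expect_true(all(is.finite(df$alpha[-1])))
  unlink(path)

  empty <- structure(list(frames = list()), class = "spindle_track")
  bad_path <- tempfile(fileext = ".csv")
  expect_error(write_tracks(empty, bad_path), "empty")
  expect_false(file.exists(bad_path))
})

test_that("run configuration files provide calibration and overrides", {
  cfg <- tempfile(fileext = ".json")
  jsonlite::write_json(list(pixel_size_um = 0.05, z_step_um = 2, dt_min = 3,
                            channel_names = c("spindle", "cortex"),
                            n_slices = 3),
                       cfg, auto_unbox = TRUE)
  rc <- read_run_config(cfg)
  expect_equal(rc$calibration$pixel_size_um, 0.05)
  expect_equal(rc$channel_names, c("spindle", "cortex"))
  expect_equal(rc$params$n_slices, 3)
  jsonlite::write_json(list(pixel_size_um = 0.05), cfg, auto_unbox = TRUE)
  expect_error(read_run_config(cfg), "z_step_um")
  unlink(cfg)

  expect_error(calibration(pixel_size_um = 0), "positive")
  expect_error(movie(list(array(0, c(2, 2, 4, 4))), calibration()), "named")
  expect_error(mask_stack(array(-1, c(1, 1, 2, 2)), "spindle"), ">= 0")
})
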