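#' Acquisition calibration
#'
#' Physical calibration of a time-lapse z-stack: lateral pixel size,
#' axial step between slices, and frame interval. Calibration is supplied
#' explicitly (or through a config file, see [read_run_config()]) rather
#' than parsed from TIFF tags, which vary by writer dialect.
#'
#' @param pixel_size_um lateral size of one pixel (micrometres); typical
#'   spinning-disk values are 0.04-0.07.
#' @param z_step_um axial spacing between slices (micrometres); the
#'   reference regime uses 2.
#' @param dt_min frame interval in minutes; the reference regime uses 3.
#' @return An object of class `"spindle_calibration"`.
#' @export
calibration <- function(pixel_size_um = 0.06887, z_step_um = 2, dt_min = 3) {
  vals <- c(pixel_size_um, z_step_um, dt_min)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("calibration: pixel size, z step and frame interval must all be strictly positive")
  }
  structure(list(pixel_size_um = pixel_size_um, z_step_um = z_step_um,
                 dt_min = dt_min),
            class = "spindle_calibration")
}

#' @export
print.spindle_calibration <- function(x, ...) {
  cat(sprintf("Calibration: %.5f um/px, z step %.3f um, frame interval %.3f min\n",
              x$pixel_size_um, x$z_step_um, x$dt_min))
  invisible(x)
}

#' Multi-channel movie container
#'
#' @param channels named list of 4D numeric arrays, axes ordered
#'   `[T, Z, Y, X]`; all channels must share one shape with `T >= 1`,
#'   `Z >= 1`.
#' @param calibration a [calibration()] object.
#' @return An object of class `"spindle_movie"`.
#' @export
movie <- function(channels, calibration) {
  stopifnot(inherits(calibration, "spindle_calibration"))
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(names(channels) == "")) {
    stop("movie: channels must be a non-empty named list")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 4L)) {
    stop("movie: each channel must be a 4D array ordered T, Z, Y, X")
  }
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("movie: all channels must share an identical shape")
  }
  structure(list(channels = channels, calibration = calibration),
            class = "spindle_movie")
}

#' @export
print.spindle_movie <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("Movie: %d channel(s) [%s], T=%d, Z=%d, %dx%d px\n",
              length(x$channels),
              paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3], d[4]))
  print(x$calibration)
  invisible(x)
}

#' Per-class label stack aligned to a movie channel
#'
#' @param labels 4D integer array `[T, Z, Y, X]`, 0 = background.
#' @param class_name one of `"spindle"`, `"cortex"`, `"chromosome"`.
#' @return An object of class `"mask_stack"`.
#' @export
mask_stack <- function(labels, class_name = c("spindle", "cortex", "chromosome")) {
  class_name <- match.arg(class_name)
  labels <- as.array(labels)
  if (length(dim(labels)) != 4L) stop("mask_stack: labels must be 4D (T, Z, Y, X)")
  if (any(labels < 0)) stop("mask_stack: label values must be >= 0")
  structure(list(labels = labels, class_name = class_name),
            class = "mask_stack")
}

#' Read a multi-page TIFF movie
#'
#' Reads a multi-page TIFF into a [movie()]. Pages are assumed ordered
#' time-major, then channel, with z fastest:
#' page `((t-1) * C + (c-1)) * Z + z`. Integer intensities are preserved
#' bit-exactly (8- and 16-bit input both accepted).
#'
#' @param path TIFF file path.
#' @param calibration a [calibration()] object.
#' @param n_slices declared number of z slices per frame.
#' @param channel_names character vector naming the channels (its length
#'   sets the channel count; default one channel, `"intensity"`).
#' @return A [movie()] with axes `T, Z, Y, X`.
#' @export
read_movie <- function(path, calibration, n_slices,
                       channel_names = "intensity") {
  if (!file.exists(path)) stop("read_movie: file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_pages <- length(pages)
  n_chan <- length(channel_names)
  per_frame <- n_slices * n_chan
  if (n_pages %% per_frame != 0L) {
    stop(sprintf(
      "read_movie: dimension error - %d page(s) not divisible by Z=%d x %d channel(s) (expected a multiple of %d)",
      n_pages, n_slices, n_chan, per_frame))
  }
  n_t <- n_pages %/% per_frame
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  channels <- stats::setNames(vector("list", n_chan), channel_names)
  for (ci in seq_len(n_chan)) {
    arr <- array(0, dim = c(n_t, n_slices, ny, nx))
    for (t in seq_len(n_t)) {
      for (z in seq_len(n_slices)) {
        pg <- pages[[((t - 1L) * n_chan + (ci - 1L)) * n_slices + z]]
        arr[t, z, , ] <- pg
      }
    }
    channels[[ci]] <- arr
  }
  movie(channels, calibration)
}

#' Write a movie (or one channel) as a multi-page TIFF
#'
#' Inverse of [read_movie()]: pages ordered time-major, then channel, z
#' fastest. Intensities are stored as unsigned integers of the requested
#' bit depth; values must already lie in `[0, 2^bits - 1]`.
#'
#' @param mov a [movie()].
#' @param path output path.
#' @param bits bits per sample, 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
write_movie <- function(mov, path, bits = 16L) {
  stopifnot(inherits(mov, "spindle_movie"), bits %in% c(8L, 16L))
  d <- dim(mov$channels[[1]])
  top <- 2^bits - 1
  pages <- list()
  for (t in seq_len(d[1])) {
    for (ch in mov$channels) {
      if (max(ch) > top || min(ch) < 0) {
        stop("write_movie: intensities exceed the requested bit depth")
      }
      for (z in seq_len(d[2])) {
        pages[[length(pages) + 1L]] <- matrix(ch[t, z, , ] / top, d[3], d[4])
      }
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

#' Pad an image to a target size with low-intensity tiling
#'
#' Pads an image up to `target_size` keeping the original centered and
#' unchanged. Rather than padding with zeros (which would create an
#' artificial hard edge), the padding is tiled from the input patch with
#' the lowest pixel-intensity sum, i.e. the emptiest piece of background
#' available in the image itself. All sliding patch positions are scanned
#' (via a summed-area table); ties on the sum are broken by the smallest
#' (row, col) patch origin. The tiling is laid row-major across the whole
#' canvas before the original is placed back in the center.
#'
#' @param image 2D numeric matrix.
#' @param target_size integer `(rows, cols)`, each >= the image size.
#' @param patch_size integer `(rows, cols)`, each <= the image size
#'   (default `c(10, 10)`).
#' @return Matrix of dimension `target_size`.
#' @export
pad_image <- function(image, target_size, patch_size = c(10L, 10L)) {
  image <- as.matrix(image)
  tr <- as.integer(target_size[1]); tc <- as.integer(target_size[2])
  pr <- as.integer(patch_size[1]); pc <- as.integer(patch_size[2])
  nr <- nrow(image); nc <- ncol(image)
  if (tr < nr || tc < nc) {
    stop(sprintf("pad_image: size error - target %dx%d smaller than image %dx%d",
                 tr, tc, nr, nc))
  }
  if (pr > nr || pc > nc || pr < 1L || pc < 1L) {
    stop("pad_image: patch size must be positive and no larger than the image")
  }
  if (tr == nr && tc == nc) return(image)

  # summed-area table for O(1) patch sums at every sliding position
  sat <- apply(apply(image, 2, cumsum), 1, cumsum)   # transposed cumsum
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  sums <- sat[(pr + 1):(nr + 1), (pc + 1):(nc + 1), drop = FALSE] -
    sat[1:(nr - pr + 1), (pc + 1):(nc + 1), drop = FALSE] -
    sat[(pr + 1):(nr + 1), 1:(nc - pc + 1), drop = FALSE] +
    sat[1:(nr - pr + 1), 1:(nc - pc + 1), drop = FALSE]
  # row-major tie-break on (row, col) of the patch origin
  best <- which(sums == min(sums), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2])[1], ]
  patch <- image[best[1]:(best[1] + pr - 1L), best[2]:(best[2] + pc - 1L)]

  out <- patch[((seq_len(tr) - 1L) %% pr) + 1L, ((seq_len(tc) - 1L) %% pc) + 1L]
  r0 <- (tr - nr) %/% 2L
  c0 <- (tc - nc) %/% 2L
  out[(r0 + 1):(r0 + nr), (c0 + 1):(c0 + nc)] <- image
  out
}

#' Write a tracked spindle to CSV
#'
#' One row per accepted frame: time, the six axis endpoints and centroid
#' (micrometres), pole-to-cortex distances, frame-to-frame Euler angles and
#' displacement components (relative to the previous accepted frame; NA on
#' the first row), and whether any identity correction was applied at that
#' frame. Values are written with 17 significant digits so a read-back
#' reproduces them to better than 1e-9 relative.
#'
#' @param track a `"spindle_track"` from [track_movie()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @seealso [read_tracks()]
#' @export
write_tracks <- function(track, path) {
  stopifnot(inherits(track, "spindle_track"))
  if (length(track$frames) == 0L) {
    stop("write_tracks: track is empty, nothing to write")
  }
  n <- length(track$frames)
  ep <- function(fld, k) vapply(track$frames, function(f) f[[fld]][k], 0)
  df <- data.frame(frame = track$frame_index, time_min = track$time_min)
  for (fld in c("pole1", "pole2", "width1", "width2", "height1", "height2",
                "centroid")) {
    for (k in 1:3) {
      df[[paste0(fld, "_", c("x", "y", "z")[k])]] <- ep(fld, k)
    }
  }
  df$pole1_cortex_dist <- track$distances$d1
  df$pole2_cortex_dist <- track$distances$d2
  ang <- matrix(NA_real_, n, 6)
  if (n >= 2L) {
    for (i in 2:n) {
      e <- euler_angles(frame_rotation(track$frames[[i - 1L]], track$frames[[i]]))
      d <- decompose_displacement(track$frames[[i - 1L]], track$frames[[i]])
      ang[i, ] <- c(e$alpha_deg, e$beta_deg, e$gamma_deg,
                    d$delta_lg, d$delta_eq, d$delta_ax)
    }
  }
  df$alpha <- ang[, 1]; df$beta <- ang[, 2]; df$gamma <- ang[, 3]
  df$delta_lg <- ang[, 4]; df$delta_eq <- ang[, 5]; df$delta_ax <- ang[, 6]
  df$corrections_applied <- track$frame_index %in% track$corrections$frame

  num <- vapply(df, is.numeric, TRUE)
  out <- df
  out[num] <- lapply(df[num], function(v) {
    ifelse(is.na(v), "NA", sprintf("%.17g", v))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a track CSV written by [write_tracks()]
#'
#' @param path CSV path.
#' @return A data.frame with numeric columns restored.
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop("read_tracks: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in setdiff(names(df), "corrections_applied")) {
    df[[nm]] <- as.numeric(df[[nm]])
  }
  df$corrections_applied <- as.logical(df$corrections_applied)
  df
}

#' Read a run configuration file
#'
#' JSON config with keys `pixel_size_um`, `z_step_um`, `dt_min` and
#' optionally `channel_names` plus free-form module parameter overrides.
#'
#' @param path JSON file path.
#' @return A list with `calibration` (a [calibration()]),
#'   `channel_names`, and `params` (remaining entries).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("read_run_config: file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("pixel_size_um", "z_step_um", "dt_min")
  if (!all(need %in% names(cfg))) {
    stop("read_run_config: config must define ",
         paste(setdiff(need, names(cfg)), collapse = ", "))
  }
  list(
    calibration = calibration(cfg$pixel_size_um, cfg$z_step_um, cfg$dt_min),
    channel_names = if (!is.null(cfg$channel_names)) cfg$channel_names
    else "intensity",
    params = cfg[setdiff(names(cfg), c(need, "channel_names"))]
  )
}
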