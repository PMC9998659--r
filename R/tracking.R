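#' Refine spindle pole positions against the segmentation mask
#'
#' The minimum-volume ellipsoid tends to overestimate spindle length, which
#' displaces the predicted poles outward along the pole-to-pole axis. This
#' refinement samples the (max-projected) spindle mask along the full
#' pole-axis line at half-pixel steps with nearest-pixel lookup, finds the
#' first and last foreground occurrences, and moves each pole to those
#' crossings. An overshooting estimate (the usual case) therefore strictly
#' shrinks to the mask boundary; an undershooting one extends to it. The
#' pole z-coordinates follow the same 3D axis line.
#'
#' @param spindle_mask 2D binary/integer matrix (rows = y, cols = x),
#'   typically the max projection of the spindle mask over z.
#' @param poles list or 2-row matrix with the two pole positions
#'   (micrometres, lab frame).
#' @param pixel_size_um lateral pixel size used to map micrometres to
#'   pixel indices.
#' @return A list with refined `p1`, `p2` (micrometres), logical
#'   `refined` (FALSE when both poles already sat on the mask boundary) and
#'   `scale` (refined length / original length; <= 1 whenever the initial
#'   axis covered the mask).
#' @export
refine_poles <- function(spindle_mask, poles, pixel_size_um) {
  mask <- as.matrix(spindle_mask) > 0
  if (!any(mask)) stop("refine_poles: spindle mask is empty")
  if (is.list(poles)) poles <- rbind(poles[[1]], poles[[2]])
  p1 <- as.numeric(poles[1, ]); p2 <- as.numeric(poles[2, ])
  axis_len <- sqrt(sum((p2 - p1)^2))
  if (axis_len == 0) stop("refine_poles: poles must define a non-degenerate axis")

  # sample the whole pole-axis line across the canvas (not only between the
  # initial poles): an overshooting estimate shrinks to the mask boundary,
  # an undershooting one extends to it
  diag_um <- sqrt(sum((dim(mask) * pixel_size_um)^2))
  ext <- diag_um / axis_len
  # half-pixel sampling density along the extended axis
  n_steps <- max(2L, as.integer(ceiling(2 * (1 + 2 * ext) * axis_len /
                                          pixel_size_um)) + 1L)
  tt <- seq(-ext, 1 + ext, length.out = n_steps)
  px <- outer(1 - tt, p1) + outer(tt, p2)   # n x 3 points along the axis
  col_idx <- as.integer(round(px[, 1] / pixel_size_um)) + 1L
  row_idx <- as.integer(round(px[, 2] / pixel_size_um)) + 1L
  ok <- row_idx >= 1L & row_idx <= nrow(mask) &
    col_idx >= 1L & col_idx <= ncol(mask)
  fg <- logical(n_steps)
  fg[ok] <- mask[cbind(row_idx[ok], col_idx[ok])]
  if (!any(fg)) {
    stop("refine_poles: refinement error - sampled axis is entirely background")
  }
  i1 <- which(fg)[1]
  i2 <- which(fg)[length(which(fg))]
  q1 <- px[i1, ]
  q2 <- px[i2, ]
  new_len <- sqrt(sum((q2 - q1)^2))
  moved <- max(sqrt(sum((q1 - p1)^2)), sqrt(sum((q2 - p2)^2)))
  list(p1 = q1, p2 = q2,
       refined = moved > pixel_size_um / 2,
       scale = new_len / axis_len)
}

#' Identity-consistent relabelling of spindle axis endpoints
#'
#' Six-point tracking: for each of the three principal-axis endpoint pairs
#' (poles, width, height) independently, compares the 2x2 Euclidean
#' distance matrix between the current and previous frame's endpoints and
#' swaps the current labels whenever the crossed pairing gives the smaller
#' total displacement. Ties (perfectly symmetric configurations) keep the
#' previous labels. Distances are 3D, in micrometres, so anisotropic z is
#' naturally included.
#'
#' @param current,previous [spindle_axes()] objects at consecutive
#'   (accepted) frames.
#' @return A list with `axes` (the relabelled current frame) and
#'   `corrections`, a named logical vector (`length`, `width`, `height`)
#'   marking the axes whose endpoints were swapped.
#' @export
assign_identities <- function(current, previous) {
  stopifnot(inherits(current, "spindle_axes"), inherits(previous, "spindle_axes"))
  pairs <- list(length = c("pole1", "pole2"),
                width = c("width1", "width2"),
                height = c("height1", "height2"))
  out <- current
  corrections <- c(length = FALSE, width = FALSE, height = FALSE)
  for (ax in names(pairs)) {
    nm <- pairs[[ax]]
    c1 <- current[[nm[1]]]; c2 <- current[[nm[2]]]
    p1 <- previous[[nm[1]]]; p2 <- previous[[nm[2]]]
    straight <- sum((c1 - p1)^2) + sum((c2 - p2)^2)
    crossed <- sum((c1 - p2)^2) + sum((c2 - p1)^2)
    if (crossed < straight) {
      out[[nm[1]]] <- c2
      out[[nm[2]]] <- c1
      corrections[[ax]] <- TRUE
    }
  }
  list(axes = out, corrections = corrections)
}

#' Track a spindle through a movie with identity-consistent poles
#'
#' Integrates the per-frame geometry into a tracked time series: for each
#' frame, principal-axis endpoints are derived from the spindle ellipsoid,
#' poles are refined against the spindle mask (when provided), endpoint
#' identities are matched to the last accepted frame ([assign_identities()],
#' so corrections propagate until the next swap), and pole-to-cortex
#' distances are ray-traced. Frames whose poles fall outside the cortex or
#' whose refinement fails are excluded and logged rather than silently
#' clamped, and identity matching then skips to the last accepted frame.
#'
#' @param per_frame list with one element per frame; each element a list
#'   with `spindle` ([ellipsoid3d()]), optional `mask` (2D matrix, max
#'   projection of the spindle mask) and `cortex` ([ellipsoid3d()]).
#' @param calibration a [calibration()] object (pixel size and frame
#'   interval).
#' @return An object of class `"spindle_track"`: `frames` (accepted
#'   [spindle_axes()]), `frame_index`, `time_min`, `distances`
#'   (data.frame `frame`, `d1`, `d2`), `corrections` (data.frame `frame`,
#'   `axis`), `excluded` (data.frame `frame`, `reason`), `refined`
#'   (logical per accepted frame), `dt_min`, `pixel_size_um`.
#' @seealso [summarize_track()], [write_tracks()]
#' @export
track_movie <- function(per_frame, calibration) {
  if (length(per_frame) < 1L) stop("track_movie: at least one frame is required")
  stopifnot(inherits(calibration, "spindle_calibration"))
  px <- calibration$pixel_size_um
  frames <- list()
  frame_index <- integer(0)
  refined_flags <- logical(0)
  corrections <- data.frame(frame = integer(0), axis = character(0))
  excluded <- data.frame(frame = integer(0), reason = character(0))
  dist_rows <- list()

  prev <- NULL
  parity <- c(length = FALSE, width = FALSE, height = FALSE)
  for (t in seq_along(per_frame)) {
    fr <- per_frame[[t]]
    axes <- principal_axes_endpoints(fr$spindle)
    was_refined <- FALSE
    if (!is.null(fr$mask)) {
      ref <- tryCatch(
        refine_poles(fr$mask, list(axes$pole1, axes$pole2), px),
        error = function(e) e
      )
      if (inherits(ref, "error")) {
        excluded <- rbind(excluded,
                          data.frame(frame = t, reason = conditionMessage(ref)))
        next
      }
      half <- ref$scale * fr$spindle$semi_axes[1]
      if (half <= fr$spindle$semi_axes[2]) {
        excluded <- rbind(excluded, data.frame(
          frame = t,
          reason = "refined length axis shorter than width axis"))
        next
      }
      ell <- ellipsoid3d((ref$p1 + ref$p2) / 2,
                         c(half, fr$spindle$semi_axes[2:3]),
                         fr$spindle$orientation)
      axes <- principal_axes_endpoints(ell)
      # orientation sign convention may flip pole labels; restore the
      # refined sampling order so refinement itself never swaps identities
      if (sum((axes$pole1 - ref$p1)^2) > sum((axes$pole1 - ref$p2)^2)) {
        tmp <- axes$pole1
        axes$pole1 <- axes$pole2
        axes$pole2 <- tmp
      }
      was_refined <- ref$refined
    }
    if (!is.null(prev)) {
      asg <- assign_identities(axes, prev)
      axes <- asg$axes
      # a correction, once applied, propagates: the raw per-frame labels
      # come from a memoryless sign convention, so only a change in swap
      # parity is a new correction event
      for (ax in names(asg$corrections)[asg$corrections != parity]) {
        corrections <- rbind(corrections, data.frame(frame = t, axis = ax))
      }
      parity <- asg$corrections
    }
    dists <- tryCatch(pole_cortex_distances(axes, fr$cortex),
                      error = function(e) e)
    if (inherits(dists, "error")) {
      excluded <- rbind(excluded,
                        data.frame(frame = t, reason = conditionMessage(dists)))
      next
    }
    frames <- c(frames, list(axes))
    frame_index <- c(frame_index, t)
    refined_flags <- c(refined_flags, was_refined)
    dist_rows[[length(dist_rows) + 1L]] <-
      data.frame(frame = t, d1 = dists$d1, d2 = dists$d2)
    prev <- axes
  }
  if (length(frames) == 0L) {
    stop("track_movie: no frame passed refinement and containment checks")
  }
  structure(
    list(frames = frames,
         frame_index = frame_index,
         time_min = (frame_index - 1L) * calibration$dt_min,
         distances = do.call(rbind, dist_rows),
         corrections = corrections,
         excluded = excluded,
         refined = refined_flags,
         dt_min = calibration$dt_min,
         pixel_size_um = px),
    class = "spindle_track"
  )
}

#' @export
print.spindle_track <- function(x, ...) {
  cat(sprintf("Tracked spindle: %d accepted frame(s), %d excluded, %d identity correction(s)\n",
              length(x$frames), nrow(x$excluded), nrow(x$corrections)))
  if (nrow(x$excluded)) {
    cat("  excluded frames:", paste(x$excluded$frame, collapse = ", "), "\n")
  }
  if (length(x$frames) >= 1L) {
    lens <- vapply(x$frames, function(f) f$length_um, 0)
    cat(sprintf("  spindle length %.2f-%.2f um; pole-cortex distances %.2f-%.2f um\n",
                min(lens), max(lens),
                min(x$distances$d1, x$distances$d2),
                max(x$distances$d1, x$distances$d2)))
  }
  invisible(x)
}

#' @export
summary.spindle_track <- function(object, ...) {
  summarize_track(object, ...)
}

#' @export
plot.spindle_track <- function(x, ...) {
  if (length(x$frames) < 2L) {
    stop("plot.spindle_track: at least 2 accepted frames are required")
  }
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(x$time_min, cbind(x$distances$d1, x$distances$d2),
                    type = "b", pch = c(1, 16), lty = 1,
                    col = c("darkorange", "black"),
                    xlab = "time (min)", ylab = "pole-cortex distance (um)",
                    main = "Pole-cortex distances", ...)
  graphics::legend("topright", c("pole 1", "pole 2"), pch = c(1, 16),
                   col = c("darkorange", "black"), bty = "n")
  s <- summarize_track(x)
  graphics::matplot(seq_len(s$n_intervals),
                    abs(s$series[, c("alpha_deg", "beta_deg", "gamma_deg")]),
                    type = "l", lty = 1,
                    col = c("firebrick", "forestgreen", "steelblue"),
                    xlab = "interval", ylab = "|angle| (deg)",
                    main = "Frame-to-frame rotation")
  graphics::legend("topright", c("alpha", "beta", "gamma"), lty = 1,
                   col = c("firebrick", "forestgreen", "steelblue"), bty = "n")
  invisible(x)
}
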