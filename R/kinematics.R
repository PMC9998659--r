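#' Elementary rotation matrices and their ZYX composition
#'
#' Builds the right-handed rotation matrices about the x, y and z axes and
#' their composition `R = Rz(gamma) %*% Ry(beta) %*% Rx(alpha)`, the
#' convention used throughout for spindle motion: `alpha` is tumbling about
#' the spindle x-axis, `beta` rolling about y, `gamma` rotation about z.
#'
#' @param alpha_deg,beta_deg,gamma_deg angles in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rotation_zyx <- function(alpha_deg, beta_deg, gamma_deg) {
  rot_z(gamma_deg) %*% rot_y(beta_deg) %*% rot_x(alpha_deg)
}

rot_x <- function(deg) {
  r <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(r), sin(r), 0, -sin(r), cos(r)), 3, 3)
}
rot_y <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), 0, -sin(r), 0, 1, 0, sin(r), 0, cos(r)), 3, 3)
}
rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}

#' Frame-to-frame spindle rotation matrix
#'
#' The rotation carrying the previous frame's spindle axis triad onto the
#' current frame's: `R = A_t %*% t(A_(t-1))`, where the columns of `A` are
#' the unit length/width/height directions. Requires identity-consistent
#' axes (run [assign_identities()] first), otherwise a label swap would
#' masquerade as a 180-degree rotation.
#'
#' @param previous,current [spindle_axes()] objects at consecutive frames.
#' @return An orthonormal 3x3 matrix with determinant +1 (within 1e-9).
#' @export
frame_rotation <- function(previous, current) {
  stopifnot(inherits(previous, "spindle_axes"), inherits(current, "spindle_axes"))
  A_prev <- axes_triad(previous)
  A_cur <- axes_triad(current)
  for (A in list(A_prev, A_cur)) {
    if (max(abs(crossprod(A) - diag(3))) > 1e-6) {
      stop("frame_rotation: axis triad is not orthonormal within tolerance")
    }
  }
  R <- A_cur %*% t(A_prev)
  # project onto SO(3) to shed accumulated rounding
  sv <- svd(R)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {
    stop("frame_rotation: triads have opposite handedness (identity assignment missing?)")
  }
  R
}

#' Euler angles of a rotation matrix (ZYX convention)
#'
#' Extracts `(alpha, beta, gamma)` such that
#' `R = Rz(gamma) %*% Ry(beta) %*% Rx(alpha)` ([rotation_zyx()]), using
#' two-argument arctangents. The extraction is defined by exact round-trip
#' consistency with the composition: recomposing the returned angles
#' reproduces `R` to machine precision away from gimbal lock.
#'
#' At gimbal lock (`|cos(beta)| < 1e-9`, i.e. `beta = +/-90` degrees) only
#' `alpha - gamma` (or `alpha + gamma`) is determined; the convention here
#' sets `gamma = 0`, folds the free angle into `alpha`, and flags the
#' result (`gimbal_lock = TRUE`).
#'
#' @param R orthonormal 3x3 matrix, `det(R) = +1`.
#' @return A list of class `"rotation_angles"`: `alpha_deg`, `beta_deg`,
#'   `gamma_deg` in `(-180, 180]`, and `gimbal_lock` flag.
#' @examples
#' euler_angles(rotation_zyx(10, 20, 30))
#' @export
euler_angles <- function(R) {
  R <- as.matrix(R)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0) {
    stop("euler_angles: R must be orthonormal with determinant +1")
  }
  cb <- sqrt(R[3, 2]^2 + R[3, 3]^2)   # |cos(beta)|
  if (cb < 1e-9) {
    beta <- if (-R[3, 1] > 0) 90 else -90
    # R[1,2] = sin(alpha -/+ gamma) patterns; fold free angle into alpha
    alpha <- if (beta > 0) {
      atan2(R[1, 2], R[2, 2]) * 180 / pi
    } else {
      atan2(-R[1, 2], R[2, 2]) * 180 / pi
    }
    ang <- list(alpha_deg = alpha, beta_deg = beta, gamma_deg = 0,
                gimbal_lock = TRUE)
  } else {
    ang <- list(
      alpha_deg = atan2(R[3, 2], R[3, 3]) * 180 / pi,
      beta_deg = atan2(-R[3, 1], cb) * 180 / pi,
      gamma_deg = atan2(R[2, 1], R[1, 1]) * 180 / pi,
      gimbal_lock = FALSE
    )
  }
  class(ang) <- "rotation_angles"
  ang
}

#' @export
print.rotation_angles <- function(x, ...) {
  cat(sprintf("Euler angles (ZYX): alpha %.4f, beta %.4f, gamma %.4f deg%s\n",
              x$alpha_deg, x$beta_deg, x$gamma_deg,
              if (isTRUE(x$gimbal_lock)) " [gimbal lock]" else ""))
  invisible(x)
}

#' Decompose spindle displacement into longitudinal / equatorial / axial parts
#'
#' Projects the frame-to-frame displacement of a reference point (spindle
#' centroid by default, optionally a pole) onto the previous frame's unit
#' length, width and height axes, yielding signed components
#' `delta_lg`, `delta_eq`, `delta_ax` (micrometres) and their fractions of
#' the total Euclidean displacement. Because the three axes are
#' orthonormal, `f_lg^2 + f_eq^2 + f_ax^2 == 1` for any nonzero motion.
#'
#' @param previous,current identity-consistent [spindle_axes()] at
#'   consecutive frames.
#' @param reference which point to follow: `"centroid"` (default),
#'   `"pole1"` or `"pole2"`.
#' @return A list of class `"displacement_decomposition"`: `delta_lg`,
#'   `delta_eq`, `delta_ax`, `f_lg`, `f_eq`, `f_ax`, `displacement_um`,
#'   `zero_motion` flag.
#' @export
decompose_displacement <- function(previous, current,
                                   reference = c("centroid", "pole1", "pole2")) {
  stopifnot(inherits(previous, "spindle_axes"), inherits(current, "spindle_axes"))
  reference <- match.arg(reference)
  delta <- current[[reference]] - previous[[reference]]
  U <- axes_triad(previous)   # columns: length, width, height
  comp <- drop(crossprod(U, delta))
  nrm <- sqrt(sum(delta^2))
  if (nrm == 0) {
    fr <- c(0, 0, 0)
    zero <- TRUE
  } else {
    fr <- abs(comp) / nrm
    zero <- FALSE
  }
  structure(
    list(delta_lg = comp[1], delta_eq = comp[2], delta_ax = comp[3],
         f_lg = fr[1], f_eq = fr[2], f_ax = fr[3],
         displacement_um = nrm, zero_motion = zero),
    class = "displacement_decomposition"
  )
}

# Inverse empirical CDF under the nearest-rank (smallest value with
# ECDF >= p) convention: sorted[ceiling(p * n)].
ecdf_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  x[max(1L, min(n, as.integer(ceiling(p * n))))]
}

#' Per-movie kinematic summary of a tracked spindle
#'
#' Computes per-interval rotation angles and displacement decompositions
#' along a tracked movie and summarises them: median absolute `alpha`,
#' `beta`, `gamma` per frame interval, median displacement fractions, the
#' inverse-ECDF value of each |angle| series at a configurable percentile,
#' and cumulative rotation series.
#'
#' @param track a `"spindle_track"` object from [track_movie()].
#' @param percentile ECDF probe level (default 0.75).
#' @param reference displacement reference point, see
#'   [decompose_displacement()].
#' @param per_minute if `TRUE`, angle series are divided by the frame
#'   interval in minutes (rates per minute); default reports per frame
#'   interval.
#' @return A list of class `"spindle_track_summary"` with the per-interval
#'   series (`data.frame`) and the summary statistics.
#' @export
summarize_track <- function(track, percentile = 0.75,
                            reference = "centroid", per_minute = FALSE) {
  stopifnot(inherits(track, "spindle_track"))
  frames <- track$frames
  if (length(frames) < 2L) {
    stop("summarize_track: at least 2 accepted frames are required")
  }
  dt <- if (!is.null(track$dt_min)) track$dt_min else 1
  n <- length(frames)
  rows <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    R <- frame_rotation(frames[[i]], frames[[i + 1L]])
    ang <- euler_angles(R)
    dec <- decompose_displacement(frames[[i]], frames[[i + 1L]],
                                  reference = reference)
    rows[[i]] <- data.frame(
      interval = i,
      alpha_deg = ang$alpha_deg, beta_deg = ang$beta_deg,
      gamma_deg = ang$gamma_deg, gimbal_lock = ang$gimbal_lock,
      delta_lg = dec$delta_lg, delta_eq = dec$delta_eq,
      delta_ax = dec$delta_ax,
      f_lg = dec$f_lg, f_eq = dec$f_eq, f_ax = dec$f_ax,
      displacement_um = dec$displacement_um
    )
  }
  series <- do.call(rbind, rows)
  scale <- if (per_minute) 1 / dt else 1
  abs_ang <- abs(series[, c("alpha_deg", "beta_deg", "gamma_deg")]) * scale
  out <- list(
    series = series,
    n_intervals = n - 1L,
    dt_min = dt,
    per_minute = per_minute,
    median_abs_angles_deg = vapply(abs_ang, stats::median, 0),
    ecdf_percentile = percentile,
    ecdf_angles_deg = vapply(abs_ang, ecdf_quantile, 0, p = percentile),
    median_fractions = vapply(series[, c("f_lg", "f_eq", "f_ax")],
                              stats::median, 0),
    cumulative_angles_deg = lapply(abs_ang, cumsum),
    median_displacement_um = stats::median(series$displacement_um)
  )
  class(out) <- "spindle_track_summary"
  out
}

#' @export
print.spindle_track_summary <- function(x, ...) {
  unit <- if (x$per_minute) "deg/min" else sprintf("deg/%g min", x$dt_min)
  cat(sprintf("Spindle kinematics over %d intervals (%s)\n",
              x$n_intervals, unit))
  m <- x$median_abs_angles_deg
  cat(sprintf("  median |alpha| %.3f  |beta| %.3f  |gamma| %.3f\n",
              m[1], m[2], m[3]))
  f <- x$median_fractions
  cat(sprintf("  median fractions: f_lg %.3f  f_eq %.3f  f_ax %.3f\n",
              f[1], f[2], f[3]))
  cat(sprintf("  median displacement %.3f um per interval\n",
              x$median_displacement_um))
  invisible(x)
}
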