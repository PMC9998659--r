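# End-to-end reconstruction: masks + intensities -> per-frame ellipsoids
# -> tracked spindle. This is the flow behind the command-line `track`.

# Boundary pixel coordinates (um) of each z-slice of a cortex mask stack
# for one frame, lifted to the slice's physical z. Only convex-hull
# vertices are kept per slice: the minimum-volume enclosing ellipsoid
# depends on the hull only, and this keeps the fit fast.
cortex_boundary_points <- function(cortex_masks_tz, calibration) {
  nz <- dim(cortex_masks_tz)[1]
  px <- calibration$pixel_size_um
  pts <- list()
  for (z in seq_len(nz)) {
    m <- cortex_masks_tz[z, , ] > 0
    if (!any(m)) next
    bnd <- trace_boundary(m)
    hull <- bnd[grDevices::chull(bnd[, 2], bnd[, 1]), , drop = FALSE]
    pts[[length(pts) + 1L]] <- cbind(
      x = (hull[, 2] - 1) * px,
      y = (hull[, 1] - 1) * px,
      z = (z - 1) * calibration$z_step_um
    )
  }
  if (length(pts) == 0L) stop("cortex_boundary_points: all cortex masks are empty")
  do.call(rbind, pts)
}

#' Reconstruct the cortex ellipsoid from sparse z-slice masks
#'
#' Two reconstructions are available. `"profile"` (default) fits an
#' enclosing ellipse to each slice's boundary and solves the quadratic
#' axial profile `A(z)^2 = A_eq^2 * (1 - ((z - z0)/c)^2)` for the axial
#' center `z0` and semi-axis `c`; for an ellipsoidal cell sampled on >= 3
#' planes this recovers the true ellipsoid exactly, and it degrades
#' gracefully to a spherical axial prior (`c` = mean in-plane radius)
#' when the profile is non-informative (slices on one side of the
#' equator, or heavy noise). `"mvee"` feeds all boundary pixels, lifted
#' to their slice z, jointly to [fit_mvee()]; note that with very few
#' slices near the equator the minimum-volume solution is strongly
#' disc-flattened (the axial semi-axis collapses and the in-plane axes
#' inflate), which biases in-plane ray-traced distances.
#'
#' @param cortex_masks_zyx 3D binary array `[Z, Y, X]` for one frame.
#' @param calibration a [calibration()].
#' @param method `"profile"` or `"mvee"`.
#' @param mvee_tolerance tolerance for the `"mvee"` path.
#' @return An [ellipsoid3d()].
#' @export
fit_cortex_ellipsoid <- function(cortex_masks_zyx, calibration,
                                 method = c("profile", "mvee"),
                                 mvee_tolerance = 1e-4) {
  method <- match.arg(method)
  if (method == "mvee") {
    return(fit_mvee(cortex_boundary_points(cortex_masks_zyx, calibration),
                    tolerance = mvee_tolerance))
  }
  nz <- dim(cortex_masks_zyx)[1]
  px <- calibration$pixel_size_um
  fits <- list()
  for (z in seq_len(nz)) {
    m <- cortex_masks_zyx[z, , ] > 0
    if (!any(m)) next
    bnd <- trace_boundary(m)
    ell <- fit_ellipse_2d(cbind((bnd[, 2] - 1) * px, (bnd[, 1] - 1) * px))
    fits[[length(fits) + 1L]] <- list(z = (z - 1) * calibration$z_step_um,
                                      ellipse = ell)
  }
  if (length(fits) == 0L) stop("fit_cortex_ellipsoid: all cortex masks are empty")
  zs <- vapply(fits, function(f) f$z, 0)
  Asq <- vapply(fits, function(f) f$ellipse$semi_axes[1]^2, 0)
  Bsq <- vapply(fits, function(f) f$ellipse$semi_axes[2]^2, 0)
  k_eq <- which.max(Asq)
  eq <- fits[[k_eq]]$ellipse
  rad_mean <- mean(eq$semi_axes)
  z0 <- fits[[k_eq]]$z
  cax <- rad_mean     # spherical axial prior
  Aeq <- eq$semi_axes[1]
  Beq <- eq$semi_axes[2]
  if (length(fits) >= 3L) {
    # quadratic profile fit, averaged over the two in-plane axes
    qf <- stats::lm.fit(cbind(1, c(zs, zs), c(zs^2, zs^2)), c(Asq, Bsq))
    co <- qf$coefficients
    # r^2(z) = alpha + beta z + gamma z^2 with gamma = -A^2/c^2
    if (is.finite(co[3]) && co[3] < 0) {
      z0_hat <- -co[2] / (2 * co[3])
      # profile is shared; recover c from the mean-square equatorial radius
      msq <- co[1] - co[2]^2 / (4 * co[3])
      c_hat <- sqrt(-msq / co[3])
      if (is.finite(z0_hat) && is.finite(c_hat) && c_hat > 0 &&
          z0_hat > min(zs) - c_hat && z0_hat < max(zs) + c_hat) {
        z0 <- z0_hat
        cax <- c_hat
        # rescale the equator-slice axes up to the true equator
        s <- sqrt(pmax(1 - ((fits[[k_eq]]$z - z0) / cax)^2, 1e-6))
        Aeq <- eq$semi_axes[1] / s
        Beq <- eq$semi_axes[2] / s
      }
    }
  }
  th <- eq$angle_deg * pi / 180
  orient <- cbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
  ellipsoid3d(c(eq$center, z0), c(Aeq, Beq, cax), orient)
}

#' Reconstruct one frame's spindle and cortex ellipsoids
#'
#' Cortex: [fit_cortex_ellipsoid()] on the per-slice cortex masks.
#' Spindle: the brightest masked slice of the fluorescent channel is
#' converted to a 3D point cloud with [reconstruct_spindle_points()]
#' (top 30 percent brightest mask pixels, PSF axial inversion) and fitted
#' with [fit_mvee()].
#'
#' @param spindle_zyx,cortex_mask_zyx,spindle_mask_zyx 3D arrays
#'   `[Z, Y, X]` for one frame: fluorescent intensities, cortex mask,
#'   spindle mask.
#' @param psf a [psf_model()].
#' @param calibration a [calibration()].
#' @param top_fraction brightest-pixel fraction kept (default 0.30).
#' @param mvee_tolerance MVEE convergence tolerance (default 1e-4).
#' @param cortex_method cortex reconstruction, see
#'   [fit_cortex_ellipsoid()].
#' @return A list with `spindle`, `cortex` ([ellipsoid3d()]) and `mask`
#'   (2D max-projected spindle mask, for pole refinement).
#' @export
reconstruct_frame <- function(spindle_zyx, cortex_mask_zyx, spindle_mask_zyx,
                              psf, calibration, top_fraction = 0.30,
                              mvee_tolerance = 1e-4,
                              cortex_method = "profile") {
  stopifnot(inherits(psf, "psf_model"),
            inherits(calibration, "spindle_calibration"))
  cortex <- fit_cortex_ellipsoid(cortex_mask_zyx, calibration,
                                 method = cortex_method,
                                 mvee_tolerance = mvee_tolerance)
  nz <- dim(spindle_zyx)[1]
  # brightest slice = largest maximum intensity inside the mask
  peak <- vapply(seq_len(nz), function(z) {
    m <- spindle_mask_zyx[z, , ] > 0
    if (!any(m)) return(-Inf)
    max(spindle_zyx[z, , ][m])
  }, 0)
  zbest <- which.max(peak)
  if (!is.finite(peak[zbest])) stop("reconstruct_frame: spindle mask is empty in every slice")
  pts <- reconstruct_spindle_points(
    spindle_zyx[zbest, , ], spindle_mask_zyx[zbest, , ], psf,
    pixel_size_um = calibration$pixel_size_um,
    top_fraction = top_fraction,
    slice_z_um = (zbest - 1) * calibration$z_step_um
  )
  spindle <- fit_mvee(pts, tolerance = mvee_tolerance)
  proj <- apply(spindle_mask_zyx > 0, c(2, 3), any)
  list(spindle = spindle, cortex = cortex, mask = proj)
}

#' Run the full tracking pipeline on a movie plus masks
#'
#' Per frame: [reconstruct_frame()], then [track_movie()] (principal-axis
#' endpoints, pole refinement, six-point identity assignment, ray-traced
#' pole-cortex distances).
#'
#' @param mov a [movie()] with a `spindle` channel (or the single
#'   channel).
#' @param spindle_masks,cortex_masks 4D binary arrays `[T, Z, Y, X]`
#'   aligned to the movie.
#' @param psf a [psf_model()]; if missing, a model from the default
#'   [optics_config()] Gaussian parameters is used.
#' @param top_fraction brightest-pixel fraction for the spindle cloud.
#' @param spindle_channel channel name (default `"spindle"`, falling back
#'   to the first channel).
#' @param cortex_method cortex reconstruction, see
#'   [fit_cortex_ellipsoid()].
#' @return A `"spindle_track"` object.
#' @export
track_pipeline <- function(mov, spindle_masks, cortex_masks, psf = NULL,
                           top_fraction = 0.30, spindle_channel = "spindle",
                           cortex_method = "profile") {
  stopifnot(inherits(mov, "spindle_movie"))
  if (is.null(psf)) psf <- default_psf_model(mov$calibration)
  ch <- if (spindle_channel %in% names(mov$channels)) {
    mov$channels[[spindle_channel]]
  } else {
    mov$channels[[1]]
  }
  nt <- dim(ch)[1]
  frame_zyx <- function(arr4, t) {
    array(arr4[t, , , , drop = FALSE], dim = dim(arr4)[2:4])
  }
  per_frame <- vector("list", nt)
  for (t in seq_len(nt)) {
    rec <- reconstruct_frame(
      frame_zyx(ch, t),
      frame_zyx(cortex_masks, t),
      frame_zyx(spindle_masks, t),
      psf, mov$calibration, top_fraction = top_fraction,
      cortex_method = cortex_method
    )
    per_frame[[t]] <- list(spindle = rec$spindle, cortex = rec$cortex,
                           mask = rec$mask)
  }
  track_movie(per_frame, mov$calibration)
}

#' Default Gaussian PSF model for a calibration
#'
#' Theoretical widths for the default optics ([optics_config()]):
#' `sigma_xy = 0.21 * lambda / NA` converted to pixels, and
#' `sigma_z = 0.66 * lambda * n_i / NA^2`.
#'
#' @param calibration a [calibration()].
#' @param optics an [optics_config()] (defaults).
#' @return A [psf_model()].
#' @export
default_psf_model <- function(calibration, optics = optics_config()) {
  sxy_um <- 0.21 * optics$emission_wavelength_um / optics$numerical_aperture
  sz_um <- 0.66 * optics$emission_wavelength_um * optics$immersion_index /
    optics$numerical_aperture^2
  psf_model(amplitude = 1,
            xy_center = c(0, 0),
            z_center = 0,
            sigma_x = sxy_um / calibration$pixel_size_um,
            sigma_y = sxy_um / calibration$pixel_size_um,
            sigma_z = sz_um)
}
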