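#' Optical configuration for PSF simulation
#'
#' @param numerical_aperture objective NA (default 1.42, oil immersion).
#' @param emission_wavelength_um emission wavelength in micrometres
#'   (default 0.61, mCherry-like).
#' @param immersion_index refractive index of the immersion medium
#'   (default 1.518, oil).
#' @param sample_index refractive index of the sample (default 1.38,
#'   cytoplasm-like).
#' @param z_range_um half-range of the axial sweep (default 3).
#' @param z_samples number of z planes (default 31, odd keeps the focal
#'   plane on the grid).
#' @param pixel_size_um lateral sampling (default 0.06887).
#' @param xy_size_px lateral extent of the simulated stack (default 33,
#'   odd).
#' @return An object of class `"optics_config"`.
#' @export
optics_config <- function(numerical_aperture = 1.42,
                          emission_wavelength_um = 0.61,
                          immersion_index = 1.518,
                          sample_index = 1.38,
                          z_range_um = 3,
                          z_samples = 31L,
                          pixel_size_um = 0.06887,
                          xy_size_px = 33L) {
  if (numerical_aperture <= 0 || numerical_aperture >= immersion_index) {
    stop("optics_config: NA must be positive and below the immersion index")
  }
  if (emission_wavelength_um <= 0 || pixel_size_um <= 0 || z_range_um <= 0) {
    stop("optics_config: wavelength, pixel size and z range must be positive")
  }
  if (z_samples < 3L || xy_size_px < 3L) {
    stop("optics_config: stack must have at least 3 samples per dimension")
  }
  structure(list(numerical_aperture = numerical_aperture,
                 emission_wavelength_um = emission_wavelength_um,
                 immersion_index = immersion_index,
                 sample_index = sample_index,
                 z_range_um = z_range_um,
                 z_samples = as.integer(z_samples),
                 pixel_size_um = pixel_size_um,
                 xy_size_px = as.integer(xy_size_px)),
            class = "optics_config")
}

#' Simulate a 3D point-spread function
#'
#' Generates a normalised (peak 1) PSF z-stack, laterally symmetric about
#' its center, for the configured optics. Two models are available: the
#' scalar Gibson-Lanni diffraction integral (defocus phase in the sample
#' medium, circular pupil, Bessel-J0 radial kernel) and a separable
#' Gaussian approximation with
#' `sigma_xy = 0.21 * lambda / NA` and
#' `sigma_z = 0.66 * lambda * n_i / NA^2`, which is the default, fully
#' characterised path (its axial profile is exactly the model inverted by
#' [estimate_z()]).
#'
#' @param optics an [optics_config()].
#' @param method `"gaussian"` (default) or `"gibson-lanni"`.
#' @return A 3D array `[z, y, x]` with attributes `z_um` (plane positions)
#'   and `pixel_size_um`; maximum value 1 at the stack center.
#' @export
simulate_psf <- function(optics, method = c("gaussian", "gibson-lanni")) {
  stopifnot(inherits(optics, "optics_config"))
  method <- match.arg(method)
  n_xy <- optics$xy_size_px
  n_z <- optics$z_samples
  c_xy <- (n_xy + 1) / 2
  xy <- (seq_len(n_xy) - c_xy) * optics$pixel_size_um
  z <- seq(-optics$z_range_um, optics$z_range_um, length.out = n_z)
  lambda <- optics$emission_wavelength_um
  na <- optics$numerical_aperture

  if (method == "gaussian") {
    sx <- 0.21 * lambda / na
    sz <- 0.66 * lambda * optics$immersion_index / na^2
    lat <- exp(-outer(xy^2, xy^2, "+") / (2 * sx^2))
    axial <- exp(-z^2 / (2 * sz^2))
    stack <- array(0, dim = c(n_z, n_xy, n_xy))
    for (k in seq_len(n_z)) stack[k, , ] <- axial[k] * lat
  } else {
    # scalar diffraction: I(r, z) = |int_0^1 J0(k NA r rho)
    #   exp(i k z sqrt(ns^2 - NA^2 rho^2)) rho drho|^2
    k0 <- 2 * pi / lambda
    rho <- seq(0, 1, length.out = 101)
    w <- rep(c(4, 2), length.out = 99)           # Simpson weights
    w <- c(1, w, 1) * (rho[2] - rho[1]) / 3
    ax_phase <- sqrt(pmax(optics$sample_index^2 - na^2 * rho^2, 0))
    r_grid <- sqrt(outer(xy^2, xy^2, "+"))
    r_vals <- sort(unique(as.vector(r_grid)))
    stack <- array(0, dim = c(n_z, n_xy, n_xy))
    for (k in seq_len(n_z)) {
      ph <- exp(1i * k0 * z[k] * ax_phase) * rho * w
      amp <- vapply(r_vals, function(r) {
        abs(sum(besselJ(k0 * na * r * rho, 0) * ph))^2
      }, 0)
      stack[k, , ] <- amp[match(as.vector(r_grid), r_vals)]
    }
  }
  stack <- stack / max(stack)
  attr(stack, "z_um") <- z
  attr(stack, "pixel_size_um") <- optics$pixel_size_um
  stack
}

#' Gaussian PSF model
#'
#' Parametric description of the imaging PSF: a 2D Gaussian in the focal
#' plane (independent `sigma_x`, `sigma_y`, in pixels) times a 1D Gaussian
#' along z (`sigma_z`, micrometres). `amplitude` is the Gaussian height at
#' the peak.
#'
#' @param amplitude peak height (> 0).
#' @param xy_center length-2 centroid of the brightest spot (pixels).
#' @param z_center axial focal center (micrometres).
#' @param sigma_x,sigma_y lateral widths (pixels), allowed to differ.
#' @param sigma_z axial width (micrometres).
#' @return An object of class `"psf_model"`.
#' @export
psf_model <- function(amplitude, xy_center, z_center, sigma_x, sigma_y,
                      sigma_z) {
  if (amplitude <= 0 || sigma_x <= 0 || sigma_y <= 0 || sigma_z <= 0) {
    stop("psf_model: amplitude and all sigmas must be strictly positive")
  }
  structure(list(amplitude = amplitude,
                 xy_center = as.numeric(xy_center),
                 z_center = z_center,
                 sigma_x = sigma_x, sigma_y = sigma_y, sigma_z = sigma_z),
            class = "psf_model")
}

#' @export
print.psf_model <- function(x, ...) {
  cat(sprintf("Gaussian PSF model: sigma_x %.3f px, sigma_y %.3f px, sigma_z %.3f um\n",
              x$sigma_x, x$sigma_y, x$sigma_z))
  cat(sprintf("  peak %.4g at (%.2f, %.2f) px, z_c %.3f um\n",
              x$amplitude, x$xy_center[1], x$xy_center[2], x$z_center))
  invisible(x)
}

#' Fit Gaussian profiles to an empirical bead stack
#'
#' Calibrates the [psf_model()] from a fluorescent bead z-stack: a 2D
#' Gaussian with independent lateral widths is fitted to the brightest
#' slice, and a 1D Gaussian is fitted along z through the brightest
#' lateral position. Both fits use Levenberg-Marquardt least squares.
#'
#' @param bead_stack 3D numeric array `[z, y, x]` with a unique brightest
#'   region.
#' @param z_step_um axial spacing of the stack (micrometres).
#' @return A fitted [psf_model()] (amplitude from the axial fit, i.e. the
#'   intensity at the true focal center).
#' @export
fit_psf_gaussians <- function(bead_stack, z_step_um) {
  stack <- as.array(bead_stack)
  if (length(dim(stack)) != 3L) stop("fit_psf_gaussians: bead stack must be 3D")
  if (max(stack) <= min(stack)) {
    stop("fit_psf_gaussians: fit error - stack is flat, no peak to fit")
  }
  peak <- which(stack == max(stack), arr.ind = TRUE)
  if (nrow(peak) > 1L) peak <- peak[1, , drop = FALSE]
  kz <- unname(peak[1, 1]); ky <- unname(peak[1, 2]); kx <- unname(peak[1, 3])

  sl <- stack[kz, , ]
  df2 <- data.frame(
    i = as.vector(sl),
    y = as.vector(row(sl)),
    x = as.vector(col(sl))
  )
  fit2 <- tryCatch(
    minpack.lm::nlsLM(
      i ~ A * exp(-(x - xc)^2 / (2 * sx^2) - (y - yc)^2 / (2 * sy^2)),
      data = df2,
      start = list(A = max(sl), xc = kx, yc = ky, sx = 2, sy = 2),
      lower = c(A = 1e-12, xc = 0, yc = 0, sx = 1e-3, sy = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop("fit_psf_gaussians: fit error - lateral Gaussian did not converge: ",
           conditionMessage(e))
    }
  )
  p2 <- stats::coef(fit2)

  zprof <- stack[, ky, kx]
  zpos <- (seq_along(zprof) - 1) * z_step_um
  dfz <- data.frame(i = zprof, z = zpos)
  fitz <- tryCatch(
    minpack.lm::nlsLM(
      i ~ A * exp(-(z - zc)^2 / (2 * sz^2)),
      data = dfz,
      start = list(A = max(zprof), zc = zpos[kz], sz = z_step_um),
      lower = c(A = 1e-12, zc = min(zpos) - diff(range(zpos)),
                sz = 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) {
      stop("fit_psf_gaussians: fit error - axial Gaussian did not converge: ",
           conditionMessage(e))
    }
  )
  pz <- stats::coef(fitz)
  rss <- sum(stats::resid(fit2)^2) + sum(stats::resid(fitz)^2)
  # the z profile runs through the brightest pixel, which may sit off the
  # continuous lateral center; undo that lateral attenuation so the
  # amplitude is the true peak height
  lat_att <- exp(-(kx - p2["xc"])^2 / (2 * p2["sx"]^2) -
                   (ky - p2["yc"])^2 / (2 * p2["sy"]^2))
  model <- psf_model(amplitude = unname(pz["A"] / lat_att),
                     xy_center = unname(c(p2["xc"], p2["yc"])),
                     z_center = unname(pz["zc"]),
                     sigma_x = unname(p2["sx"]),
                     sigma_y = unname(p2["sy"]),
                     sigma_z = unname(pz["sz"]))
  attr(model, "rss") <- rss
  model
}

#' Estimate axial position from normalised intensity
#'
#' Inverts the axial intensity falloff `I = exp(-((z - z_c)/sigma)^2)`:
#' given an intensity normalised to the reference profile peak, returns
#' `z_hat = sigma * sqrt(-log(I)) + z_c`, the non-negative branch of the
#' inversion. Above- versus below-focus cannot be distinguished from a
#' single intensity, so the offset sign is a global convention; the
#' downstream ellipsoid fit of a symmetric structure is insensitive to it.
#'
#' @param intensity scalar or vector in `(0, 1]` (normalised to the
#'   reference peak).
#' @param model a [psf_model()]; `sigma_z` and `z_center` are used.
#' @return Estimated z (micrometres), `>= z_center`.
#' @examples
#' m <- psf_model(1, c(0, 0), 0, 1, 1, 0.9)
#' estimate_z(exp(-1), m)  # 0.9
#' @export
estimate_z <- function(intensity, model) {
  stopifnot(inherits(model, "psf_model"))
  if (any(intensity <= 0) || any(intensity > 1)) {
    stop("estimate_z: intensity must lie in (0, 1]")
  }
  model$sigma_z * sqrt(-log(intensity)) + model$z_center
}

#' Reconstruct the spindle 3D point cloud from one slice and its mask
#'
#' Burns the segmentation mask onto the raw fluorescent slice (isolating
#' spindle pixels from neighbouring signal), keeps the brightest
#' `top_fraction` of the masked pixels, normalises them to the retained
#' maximum (the reference intensity), and converts each pixel to a 3D
#' point: lateral coordinates from the pixel grid, axial coordinate from
#' [estimate_z()] applied at the slice's physical z. The resulting cloud
#' is the input to [fit_mvee()] for the spindle ellipsoid.
#'
#' @param image 2D numeric matrix (rows = y, cols = x), the in-focus
#'   fluorescent slice.
#' @param mask 2D binary matrix of the same shape.
#' @param model a [psf_model()].
#' @param pixel_size_um lateral pixel size.
#' @param top_fraction fraction of brightest masked pixels to keep
#'   (default 0.30). Exactly `ceiling(top_fraction * n_masked)` points are
#'   returned; intensity ties are broken by pixel order.
#' @param slice_z_um physical z of the slice (default 0); the estimated
#'   offsets are added to it.
#' @return Matrix (n x 3) of `(x, y, z)` points in micrometres.
#' @export
reconstruct_spindle_points <- function(image, mask, model, pixel_size_um,
                                       top_fraction = 0.30, slice_z_um = 0) {
  image <- as.matrix(image)
  mask <- as.matrix(mask) > 0
  if (!all(dim(image) == dim(mask))) {
    stop("reconstruct_spindle_points: image and mask shapes differ")
  }
  if (!any(mask)) stop("reconstruct_spindle_points: mask is empty")
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("reconstruct_spindle_points: top_fraction must lie in (0, 1]")
  }
  idx <- which(mask)
  vals <- image[idx]
  keep_n <- as.integer(ceiling(top_fraction * length(idx)))
  keep <- idx[order(vals, decreasing = TRUE)[seq_len(keep_n)]]
  inten <- image[keep]
  ref <- max(inten)
  if (ref <= 0) {
    stop("reconstruct_spindle_points: retained pixels have non-positive intensity")
  }
  inorm <- pmin(inten / ref, 1)
  inorm[inorm <= 0] <- .Machine$double.eps
  rows <- ((keep - 1L) %% nrow(image)) + 1L
  cols <- ((keep - 1L) %/% nrow(image)) + 1L
  zoff <- estimate_z(inorm, model) - model$z_center
  cbind(x = (cols - 1L) * pixel_size_um,
        y = (rows - 1L) * pixel_size_um,
        z = slice_z_um + zoff)
}
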