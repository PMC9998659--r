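# Ground-truth synthetic movie generator. Emulates the reference
# acquisition regime: sparse z-stacks (3 slices, 2 um apart) every 3 min,
# 21 frames, with a brightfield-like cortex channel, a fluorescent spindle
# channel and a chromosome-plate channel, plus exact per-frame pose.

#' Simulation parameters
#'
#' Defaults reproduce the acquisition regime the tracking pipeline is
#' designed for: 21 frames at 3-minute intervals, three z-slices with a
#' 2-micrometre gap, 512x512 pixels at 0.06887 micrometres per pixel. The
#' default cell is a mildly eccentric mitotic cortex (in-plane
#' eccentricity about 0.3) containing an 11 x 7 x 5.5 micrometre spindle.
#'
#' @param n_frames number of time points (default 21).
#' @param n_slices z slices per frame (default 3).
#' @param z_step_um z gap (default 2).
#' @param dt_min frame interval in minutes (default 3).
#' @param image_size_px square canvas size (default 512).
#' @param pixel_size_um lateral pixel size (default 0.06887).
#' @param cortex_semi_axes_um cortex ellipsoid semi-axes (default
#'   `c(9.5, 9.0, 8.6)`).
#' @param spindle_semi_axes_um spindle semi-axes, length > width >= height
#'   (default `c(5.5, 3.5, 2.75)`).
#' @param plate_radius_um,plate_thickness_um chromosome-plate disc size
#'   (defaults 3 and 1.5).
#' @param initial_angles_deg starting Euler pose `(alpha, beta, gamma)`
#'   (default zeros: spindle long axis along lab x).
#' @param angle_increments_deg per-frame Euler increments
#'   `(d_alpha, d_beta, d_gamma)` in degrees (default zeros).
#' @param centroid_velocity_um per-frame spindle centroid displacement
#'   `(vx, vy, vz)` in micrometres (default zeros).
#' @param background intensity offset (default 100).
#' @param spindle_peak,cortex_level,plate_peak channel amplitudes.
#' @param noise_sd additive Gaussian noise sd (default 20).
#' @param gradient_amplitude amplitude of a linear left-to-right
#'   illumination ramp (default 0).
#' @param psf_sigma_xy_um,psf_sigma_z_um rendering PSF widths (defaults
#'   0.09 lateral from 0.21*lambda/NA, 0.9 axial).
#' @param seed integer RNG seed driving all randomness (default 1).
#' @return An object of class `"sim_params"`.
#' @export
sim_params <- function(n_frames = 21L, n_slices = 3L, z_step_um = 2.0,
                       dt_min = 3.0, image_size_px = 512L,
                       pixel_size_um = 0.06887,
                       cortex_semi_axes_um = c(9.5, 9.0, 8.6),
                       spindle_semi_axes_um = c(5.5, 3.5, 2.75),
                       plate_radius_um = 3.0, plate_thickness_um = 1.5,
                       initial_angles_deg = c(0, 0, 0),
                       angle_increments_deg = c(0, 0, 0),
                       centroid_velocity_um = c(0, 0, 0),
                       background = 100, spindle_peak = 3000,
                       cortex_level = 500, plate_peak = 2000,
                       noise_sd = 20, gradient_amplitude = 0,
                       psf_sigma_xy_um = 0.09, psf_sigma_z_um = 0.9,
                       seed = 1L) {
  p <- as.list(environment())
  if (any(c(p$n_frames, p$n_slices, p$image_size_px) < 1)) {
    stop("sim_params: frame, slice and image sizes must be positive")
  }
  if (any(c(p$z_step_um, p$dt_min, p$pixel_size_um) <= 0)) {
    stop("sim_params: calibration values must be strictly positive")
  }
  if (any(p$cortex_semi_axes_um <= 0) || any(p$spindle_semi_axes_um <= 0)) {
    stop("sim_params: semi-axes must be strictly positive")
  }
  s <- p$spindle_semi_axes_um
  if (!(s[1] > s[2] && s[2] >= s[3])) {
    stop("sim_params: spindle semi-axes must satisfy length > width >= height")
  }
  structure(p, class = "sim_params")
}

# Evaluate the scripted pose at frame t (1-based): cumulative Euler angles,
# centroid, and the spindle/plate ellipsoids.
scripted_pose <- function(params, t) {
  ang <- params$initial_angles_deg + (t - 1) * params$angle_increments_deg
  R <- rotation_zyx(ang[1], ang[2], ang[3])
  half_fov <- params$image_size_px * params$pixel_size_um / 2
  cortex_center <- c(half_fov, half_fov,
                     (params$n_slices - 1) / 2 * params$z_step_um)
  centroid <- cortex_center + (t - 1) * params$centroid_velocity_um
  list(angles_deg = ang, R = R, centroid = centroid,
       cortex = ellipsoid3d(cortex_center, params$cortex_semi_axes_um),
       spindle = ellipsoid3d(centroid, params$spindle_semi_axes_um, R))
}

# TRUE when the spindle ellipsoid lies strictly inside the cortex
# (checked on a dense sample of the spindle surface).
spindle_inside_cortex <- function(spindle, cortex, n = 200L) {
  gold <- pi * (3 - sqrt(5))
  k <- seq_len(n)
  zs <- 1 - 2 * (k - 0.5) / n
  r <- sqrt(pmax(0, 1 - zs^2))
  dirs <- cbind(r * cos(gold * k), r * sin(gold * k), zs)
  surf <- t(spindle$orientation %*% (t(dirs) * spindle$semi_axes)) +
    matrix(spindle$center, n, 3, byrow = TRUE)
  M <- ellipsoid_shape_matrix(cortex)
  v <- sweep(surf, 2, cortex$center)
  all(rowSums((v %*% M) * v) < 1)
}

# Gaussian blur with an explicit separable kernel; stable for sub-pixel
# sigmas where EBImage::gblur's default brush construction fails.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  EBImage::filter2(img, outer(k, k), boundary = "replicate")
}

# Slice cross-section quadratic radius^2 of an ellipsoid on the pixel grid.
grid_r2 <- function(ellipsoid, nx, pixel_size_um, z_um) {
  xs <- (seq_len(nx) - 1) * pixel_size_um
  pts <- cbind(rep(xs, each = nx), rep(xs, times = nx), z_um)  # x varies slowly
  v <- sweep(pts, 2, ellipsoid$center) %*% ellipsoid$orientation
  v <- sweep(v, 2, ellipsoid$semi_axes, "/")
  matrix(rowSums(v^2), nx, nx)   # [row = y, col = x]
}

#' Generate a synthetic ground-truth movie
#'
#' Renders, per frame and slice: the cortex channel as a brightfield-like
#' dark ring at the cortex ellipsoid's slice cross-section on a gray
#' background; the spindle channel as a smooth radial intensity falloff
#' `(1 - r^2)` inside the spindle ellipsoid, blurred laterally with the
#' rendering PSF; and a chromosome plate perpendicular to the spindle long
#' axis. Configured Gaussian noise and an optional illumination gradient
#' are added. Noise is drawn from a per-frame seed derived from the master
#' seed, so renders are order-independent and the whole movie is a pure
#' function of the parameters.
#'
#' @param params a [sim_params()].
#' @return A list with `movie` (a [movie()] with channels `cortex`,
#'   `spindle`, `chromosome`), `truth` (per-frame pose: `angles_deg`,
#'   `centroid`, `axes` ([spindle_axes()]), `spindle`/`cortex` ellipsoids,
#'   `distances` from exact ray tracing) and `masks` (clean binary
#'   `[T, Z, Y, X]` arrays for the three classes).
#' @export
generate_movie <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$image_size_px
  nt <- params$n_frames
  nz <- params$n_slices
  px <- params$pixel_size_um

  poses <- lapply(seq_len(nt), scripted_pose, params = params)
  for (t in seq_len(nt)) {
    if (!spindle_inside_cortex(poses[[t]]$spindle, poses[[t]]$cortex)) {
      stop(sprintf(
        "generate_movie: scripting error - spindle escapes the cortex at frame %d",
        t))
    }
  }

  chans <- list(cortex = array(0, c(nt, nz, n, n)),
                spindle = array(0, c(nt, nz, n, n)),
                chromosome = array(0, c(nt, nz, n, n)))
  masks <- list(cortex = array(FALSE, c(nt, nz, n, n)),
                spindle = array(FALSE, c(nt, nz, n, n)),
                chromosome = array(FALSE, c(nt, nz, n, n)))
  truth <- vector("list", nt)

  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
  })

  ramp <- matrix(rep((seq_len(n) - 1) / (n - 1) - 0.5, each = n), n, n)
  sig_px <- params$psf_sigma_xy_um / px

  for (t in seq_len(nt)) {
    pose <- poses[[t]]
    plate <- ellipsoid3d(
      pose$centroid,
      c(params$plate_radius_um, params$plate_radius_um,
        params$plate_thickness_um / 2),
      pose$R[, c(2, 3, 1)])   # plate normal along the spindle long axis
    set.seed((params$seed %% 1000000L) * 2099L + t * 7919L)
    for (z in seq_len(nz)) {
      z_um <- (z - 1) * params$z_step_um
      r2_cortex <- grid_r2(pose$cortex, n, px, z_um)
      r2_spindle <- grid_r2(pose$spindle, n, px, z_um)
      r2_plate <- grid_r2(plate, n, px, z_um)

      ring <- abs(sqrt(r2_cortex) - 1) < 0.03
      cortex_img <- matrix(params$cortex_level, n, n)
      cortex_img[ring] <- params$cortex_level * 0.3

      spindle_img <- params$spindle_peak * pmax(1 - r2_spindle, 0)
      plate_img <- params$plate_peak * pmax(1 - r2_plate, 0)
      if (sig_px > 0.05) {
        spindle_img <- gaussian_blur(spindle_img, sig_px)
        plate_img <- gaussian_blur(plate_img, sig_px)
      }

      grad <- params$gradient_amplitude * ramp
      for (nm in c("cortex", "spindle", "chromosome")) {
        base <- switch(nm, cortex = cortex_img, spindle = spindle_img,
                       chromosome = plate_img)
        img <- base + params$background + grad +
          matrix(stats::rnorm(n * n, sd = params$noise_sd), n, n)
        chans[[nm]][t, z, , ] <- pmax(img, 0)
      }
      masks$cortex[t, z, , ] <- r2_cortex <= 1
      masks$spindle[t, z, , ] <- r2_spindle <= 1
      masks$chromosome[t, z, , ] <- r2_plate <= 1
    }
    # truth endpoints follow the continuous scripted rotation, so labels
    # stay temporally consistent even when the deterministic ellipsoid
    # sign convention would flip (e.g. the long axis crossing 90 degrees)
    sa <- params$spindle_semi_axes_um
    axes <- spindle_axes(
      pole1 = pose$centroid + sa[1] * pose$R[, 1],
      pole2 = pose$centroid - sa[1] * pose$R[, 1],
      width1 = pose$centroid + sa[2] * pose$R[, 2],
      width2 = pose$centroid - sa[2] * pose$R[, 2],
      height1 = pose$centroid + sa[3] * pose$R[, 3],
      height2 = pose$centroid - sa[3] * pose$R[, 3]
    )
    dists <- pole_cortex_distances(axes, pose$cortex)
    truth[[t]] <- list(angles_deg = pose$angles_deg,
                       centroid = pose$centroid,
                       axes = axes,
                       spindle = pose$spindle,
                       cortex = pose$cortex,
                       distances = dists)
  }
  cal <- calibration(px, params$z_step_um, params$dt_min)
  list(movie = movie(chans, cal), truth = truth, masks = masks,
       params = params)
}

#' Apply a reproducible corruption to a movie
#'
#' Emulates the interfering variations real movies show: a neighbouring
#' bright object near the border, a non-uniform illumination ramp,
#' Gaussian blur, or a global intensity drop over time. Ground truth is
#' unchanged by construction.
#'
#' @param mov a [movie()].
#' @param mode one of `"neighbor_object"`, `"nonuniform_illumination"`,
#'   `"blur"`, `"intensity_drop"`.
#' @param magnitude corruption strength: blob peak intensity, relative
#'   ramp amplitude, blur sigma (pixels), or total relative drop across
#'   the movie. `0` returns the movie unchanged.
#' @param seed RNG seed for stochastic placement (default 1).
#' @return The corrupted [movie()].
#' @export
corrupt_movie <- function(mov, mode = c("neighbor_object",
                                        "nonuniform_illumination",
                                        "blur", "intensity_drop"),
                          magnitude, seed = 1L) {
  stopifnot(inherits(mov, "spindle_movie"))
  mode <- match.arg(mode)
  if (magnitude == 0) return(mov)
  d <- dim(mov$channels[[1]])
  nt <- d[1]; nz <- d[2]; ny <- d[3]; nx <- d[4]

  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  if (mode == "neighbor_object") {
    # small bright disc hugging a border, same in every channel frame
    r <- max(3, round(min(ny, nx) * 0.03))
    cy <- r + 2L
    cx <- sample.int(nx - 2L * r, 1L) + r
    blob <- outer(seq_len(ny), seq_len(nx),
                  function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
    for (nm in names(mov$channels)) {
      for (t in seq_len(nt)) for (z in seq_len(nz)) {
        sl <- mov$channels[[nm]][t, z, , ]
        sl[blob] <- sl[blob] + magnitude
        mov$channels[[nm]][t, z, , ] <- sl
      }
    }
  } else if (mode == "nonuniform_illumination") {
    ramp <- 1 + magnitude * matrix(rep((seq_len(nx) - 1) / (nx - 1) - 0.5,
                                       each = ny), ny, nx)
    for (nm in names(mov$channels)) {
      for (t in seq_len(nt)) for (z in seq_len(nz)) {
        mov$channels[[nm]][t, z, , ] <- mov$channels[[nm]][t, z, , ] * ramp
      }
    }
  } else if (mode == "blur") {
    for (nm in names(mov$channels)) {
      for (t in seq_len(nt)) for (z in seq_len(nz)) {
        mov$channels[[nm]][t, z, , ] <-
          EBImage::gblur(mov$channels[[nm]][t, z, , ], sigma = magnitude)
      }
    }
  } else if (mode == "intensity_drop") {
    fac <- 1 - magnitude * (seq_len(nt) - 1) / max(1L, nt - 1L)
    for (nm in names(mov$channels)) {
      for (t in seq_len(nt)) {
        mov$channels[[nm]][t, , , ] <- mov$channels[[nm]][t, , , ] * fac[t]
      }
    }
  }
  mov
}
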