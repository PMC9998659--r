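# Shared fixtures and independent oracles, built in code at test time.

# Random rotation matrix (uniform via QR of Gaussian matrix, det +1).
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Random non-degenerate ellipsoid.
random_ellipsoid <- function(center_range = 5, axis_range = c(0.5, 4)) {
  ellipsoid3d(runif(3, -center_range, center_range),
              sort(runif(3, axis_range[1], axis_range[2]), decreasing = TRUE),
              random_rotation())
}

# Dense numeric root scan for line-ellipsoid intersection: sample the
# surface equation g(t) along the line and bisect every sign change.
scan_line_ellipsoid <- function(p1, p2, ellipsoid, t_range = c(-10, 10),
                                n_grid = 20001) {
  M <- ellipsoid_shape_matrix(ellipsoid)
  g <- function(t) {
    p <- p1 + t * (p2 - p1) - ellipsoid$center
    drop(p %*% M %*% p) - 1
  }
  ts <- seq(t_range[1], t_range[2], length.out = n_grid)
  pts <- outer(ts, p2 - p1) + matrix(p1 - ellipsoid$center, n_grid, 3,
                                     byrow = TRUE)
  gs <- rowSums((pts %*% M) * pts) - 1
  roots <- c()
  for (i in seq_len(n_grid - 1)) {
    if (gs[i] == 0) roots <- c(roots, ts[i])
    else if (gs[i] * gs[i + 1] < 0) {
      roots <- c(roots, stats::uniroot(g, c(ts[i], ts[i + 1]),
                                       tol = 1e-13)$root)
    }
  }
  sort(unique(roots))
}

# Filled-ellipse binary mask (matrix rows = y, cols = x), 1-based center.
ellipse_mask <- function(nrow, ncol, cy, cx, ry, rx, angle_deg = 0) {
  th <- angle_deg * pi / 180
  y <- matrix(seq_len(nrow), nrow, ncol) - cy
  x <- matrix(rep(seq_len(ncol), each = nrow), nrow, ncol) - cx
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  (u / rx)^2 + (v / ry)^2 <= 1
}

# Axes of a rigid spindle pose (continuous labels).
pose_axes <- function(centroid, semi, R) {
  spindle_axes(
    pole1 = centroid + semi[1] * R[, 1], pole2 = centroid - semi[1] * R[, 1],
    width1 = centroid + semi[2] * R[, 2], width2 = centroid - semi[2] * R[, 2],
    height1 = centroid + semi[3] * R[, 3],
    height2 = centroid - semi[3] * R[, 3]
  )
}

# Swap one endpoint pair of a spindle_axes in place.
swap_axis <- function(axes, which = c("length", "width", "height")) {
  which <- match.arg(which)
  nm <- switch(which, length = c("pole1", "pole2"),
               width = c("width1", "width2"),
               height = c("height1", "height2"))
  tmp <- axes[[nm[1]]]
  axes[[nm[1]]] <- axes[[nm[2]]]
  axes[[nm[2]]] <- tmp
  axes
}

# Tiny simulation parameters used by pipeline-level unit tests (quarter
# resolution keeps each render fast while preserving the geometry).
small_sim_params <- function(...) {
  args <- utils::modifyList(
    list(n_frames = 3L, image_size_px = 256L, pixel_size_um = 0.06887 * 2),
    list(...))
  do.call(sim_params, args)
}

# Rectangular segmentation candidate on an empty canvas.
rect_candidate <- function(nrow, ncol, y0, y1, x0, x1, score = 1.0) {
  m <- matrix(FALSE, nrow, ncol)
  m[y0:y1, x0:x1] <- TRUE
  segmentation_candidate(m, score = score)
}
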