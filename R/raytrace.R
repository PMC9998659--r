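#' Line segment / ray in 3D
#'
#' Parametric line `P = p1 + t * (p2 - p1)` through two distinct points,
#' used to trace the spindle pole-to-pole axis out to the cell cortex.
#'
#' @param p1,p2 numeric length-3 points (micrometres); must differ.
#' @return An object of class `"ray_segment"`.
#' @export
ray_segment <- function(p1, p2) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  stopifnot(length(p1) == 3L, length(p2) == 3L)
  if (max(abs(p1 - p2)) == 0) {
    stop("ray_segment: p1 and p2 must be distinct points")
  }
  structure(list(p1 = p1, p2 = p2), class = "ray_segment")
}

#' Analytic line-ellipsoid intersection
#'
#' Substituting the parametric line `P = p1 + t (p2 - p1)` into the
#' ellipsoid equation gives a quadratic `chi t^2 + gamma_lin t + zeta = 0`
#' whose real roots are the intersection parameters. The number of
#' intersections follows the discriminant `gamma_lin^2 - 4 chi zeta`:
#' negative means the line misses the ellipsoid, zero means tangency
#' (one point), positive means it crosses (two points). The analytic
#' solution is exact and cheap compared with sampling the surface.
#'
#' Rotated ellipsoids are handled by transforming the line into the
#' ellipsoid's principal frame (subtract the center, rotate by the
#' transpose of the orientation), solving the axis-aligned quadratic
#' there, and mapping the roots back through the original parametric line.
#'
#' @param segment a [ray_segment()].
#' @param ellipsoid an [ellipsoid3d()].
#' @return A list of class `"intersection_result"` with `coeffs`
#'   (named `chi`, `gamma_lin`, `zeta`), `t_values` (sorted, length 0-2),
#'   `points` (matrix, one lab-frame intersection point per row) and
#'   `count` (0, 1 or 2).
#' @examples
#' s <- ray_segment(c(-2, 0, 0), c(2, 0, 0))
#' intersect_line_ellipsoid(s, ellipsoid3d(c(0, 0, 0), c(1, 1, 1)))$points
#' @export
intersect_line_ellipsoid <- function(segment, ellipsoid) {
  stopifnot(inherits(segment, "ray_segment"), inherits(ellipsoid, "ellipsoid3d"))
  Q <- ellipsoid$orientation
  ax <- ellipsoid$semi_axes
  # principal-frame coordinates of the two line points
  q1 <- drop(crossprod(Q, segment$p1 - ellipsoid$center))
  q2 <- drop(crossprod(Q, segment$p2 - ellipsoid$center))
  dq <- q2 - q1
  inv2 <- 1 / ax^2
  chi <- sum(dq^2 * inv2)
  gamma_lin <- 2 * sum(dq * q1 * inv2)
  zeta <- sum(q1^2 * inv2) - 1

  disc <- gamma_lin^2 - 4 * chi * zeta
  # normalised discriminant tolerance: exact zero is measure-zero in floats
  norm <- max(gamma_lin^2, abs(4 * chi * zeta), .Machine$double.eps)
  tol <- 1e-12
  if (disc < -tol * norm) {
    tv <- numeric(0)
  } else if (abs(disc) <= tol * norm) {
    tv <- -gamma_lin / (2 * chi)
  } else {
    r <- sqrt(disc)
    tv <- sort(c((-gamma_lin - r) / (2 * chi), (-gamma_lin + r) / (2 * chi)))
  }
  pts <- if (length(tv)) {
    t(vapply(tv, function(t) segment$p1 + t * (segment$p2 - segment$p1),
             numeric(3)))
  } else {
    matrix(numeric(0), 0, 3)
  }
  structure(
    list(coeffs = c(chi = chi, gamma_lin = gamma_lin, zeta = zeta),
         t_values = tv, points = pts, count = length(tv)),
    class = "intersection_result"
  )
}

#' Pole-to-cortex distances by ray tracing
#'
#' Extends the spindle pole-to-pole axis until it hits the cortex
#' ellipsoid on either side and reports the Euclidean distance from each
#' pole to its cortical hit point. `hit1` lies on pole1's side (beyond
#' pole1, away from pole2) and `hit2` on pole2's side.
#'
#' @param axes a [spindle_axes()] object (poles define the ray).
#' @param cortex an [ellipsoid3d()] cortex model; both poles must lie
#'   strictly inside it.
#' @return A list with `d1`, `d2` (micrometres), `hit1`, `hit2`
#'   (length-3 lab-frame points).
#' @export
pole_cortex_distances <- function(axes, cortex) {
  stopifnot(inherits(axes, "spindle_axes"), inherits(cortex, "ellipsoid3d"))
  M <- ellipsoid_shape_matrix(cortex)
  inside <- function(p) {
    v <- p - cortex$center
    drop(v %*% M %*% v) < 1
  }
  if (!inside(axes$pole1) || !inside(axes$pole2)) {
    stop("pole_cortex_distances: containment error - a spindle pole lies outside the cortex ellipsoid")
  }
  seg <- ray_segment(axes$pole1, axes$pole2)
  res <- intersect_line_ellipsoid(seg, cortex)
  if (res$count != 2L) {
    stop("pole_cortex_distances: internal geometry failure - chord through interior poles must cross twice")
  }
  # parameter t runs from pole1 (t=0) to pole2 (t=1); the hit beyond pole1
  # has t < 0, the hit beyond pole2 has t > 1
  hit1 <- res$points[which.min(res$t_values), ]
  hit2 <- res$points[which.max(res$t_values), ]
  list(d1 = sqrt(sum((axes$pole1 - hit1)^2)),
       d2 = sqrt(sum((axes$pole2 - hit2)^2)),
       hit1 = hit1, hit2 = hit2)
}
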