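#' Ellipsoid in 3D
#'
#' Constructs a 3D ellipsoid from its center, semi-axis lengths and an
#' orthonormal orientation matrix. The ellipsoid is the set of points `x`
#' with `t(x - center) %*% M %*% (x - center) <= 1`, where
#' `M = orientation %*% diag(1/semi_axes^2) %*% t(orientation)`.
#'
#' Semi-axes are stored sorted in decreasing order (`a >= b >= c`) with the
#' orientation columns permuted to match, so that column 1 always points
#' along the longest (pole-to-pole, for a spindle) axis. Column signs are
#' normalised deterministically: the first nonzero component of each column
#' is made positive, then the third column is flipped if needed so that
#' `det(orientation) == +1`. Deterministic axis labelling is what makes
#' frame-to-frame identity tracking well defined.
#'
#' @param center numeric length-3 center, in micrometres.
#' @param semi_axes numeric length-3 positive semi-axis lengths (micrometres).
#' @param orientation 3x3 orthonormal matrix; columns are the unit directions
#'   of the semi-axes. Defaults to the identity (axis-aligned ellipsoid).
#' @return An object of class `"ellipsoid3d"` with fields `center`,
#'   `semi_axes` (sorted decreasing) and `orientation` (det +1).
#' @examples
#' e <- ellipsoid3d(c(0, 0, 0), c(5, 2, 1))
#' e$semi_axes
#' @seealso [fit_mvee()], [principal_axes_endpoints()]
#' @export
ellipsoid3d <- function(center, semi_axes, orientation = diag(3)) {
  center <- as.numeric(center)
  semi_axes <- as.numeric(semi_axes)
  stopifnot(length(center) == 3L, length(semi_axes) == 3L)
  if (any(!is.finite(semi_axes)) || any(semi_axes <= 0)) {
    stop("ellipsoid3d: semi-axes must be strictly positive")
  }
  orientation <- as.matrix(orientation)
  if (!all(dim(orientation) == c(3L, 3L)) ||
      max(abs(crossprod(orientation) - diag(3))) > 1e-6) {
    stop("ellipsoid3d: orientation must be a 3x3 orthonormal matrix")
  }
  ord <- order(semi_axes, decreasing = TRUE)
  semi_axes <- semi_axes[ord]
  orientation <- orientation[, ord, drop = FALSE]
  orientation <- normalize_axis_signs(orientation)
  structure(
    list(center = center, semi_axes = semi_axes, orientation = orientation),
    class = "ellipsoid3d"
  )
}

# Make each column's first component of magnitude > 1e-12 positive, then
# restore det = +1 by flipping the last column if necessary.
normalize_axis_signs <- function(Q) {
  for (j in seq_len(ncol(Q))) {
    v <- Q[, j]
    k <- which(abs(v) > 1e-12)[1]
    if (!is.na(k) && v[k] < 0) Q[, j] <- -v
  }
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

#' @export
print.ellipsoid3d <- function(x, ...) {
  cat("3D ellipsoid\n")
  cat("  center (um):   ", paste(signif(x$center, 6), collapse = ", "), "\n")
  cat("  semi-axes (um):", paste(signif(x$semi_axes, 6), collapse = ", "), "\n")
  cat("  volume (um^3): ", signif(ellipsoid_volume(x), 6), "\n")
  invisible(x)
}

#' Ellipsoid volume
#'
#' @param ellipsoid an [ellipsoid3d()] object.
#' @return Volume `4/3 * pi * a * b * c`.
#' @export
ellipsoid_volume <- function(ellipsoid) {
  4 / 3 * pi * prod(ellipsoid$semi_axes)
}

#' Quadratic (shape) matrix of an ellipsoid
#'
#' Returns the matrix `M` for which the ellipsoid surface is
#' `t(x - center) %*% M %*% (x - center) == 1`.
#'
#' @param ellipsoid an [ellipsoid3d()] object.
#' @return A symmetric positive-definite 3x3 matrix.
#' @export
ellipsoid_shape_matrix <- function(ellipsoid) {
  Q <- ellipsoid$orientation
  Q %*% diag(1 / ellipsoid$semi_axes^2) %*% t(Q)
}

#' Minimum-volume enclosing ellipsoid (MVEE)
#'
#' Fits the smallest-volume ellipsoid containing a 3D point cloud, the
#' geometric primitive behind both the cell-cortex reconstruction (boundary
#' pixels of each z-slice lifted to their physical z) and the spindle
#' reconstruction (PSF-derived 3D spindle point cloud).
#'
#' The fit solves the dual D-optimal design problem with Khachiyan's
#' barycentric coordinate-ascent iteration, accelerated with Wolfe-Atwood
#' "away" steps (weight-decrease steps), which converges much faster than
#' the plain multiplicative update at tight tolerances. On convergence every
#' input point `p` satisfies
#' `t(p - center) %*% M %*% (p - center) <= 1 + tolerance`.
#'
#' @param points numeric matrix with one 3D point per row (n x 3), n >= 4,
#'   affinely independent (not all coplanar).
#' @param tolerance convergence tolerance on the containment bound
#'   (default `1e-4`). Smaller values give a volume closer to optimal: the
#'   fitted volume exceeds the optimum by at most a factor
#'   `(1 + tolerance)^(3/2)`.
#' @param max_iter iteration cap (default 10000).
#' @return An [ellipsoid3d()] object.
#' @examples
#' cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
#' fit_mvee(cube)$semi_axes  # sphere of radius sqrt(3)
#' @references Khachiyan, L. G. (1996) Rounding of polytopes in the real
#'   number model of computation. Mathematics of Operations Research 21(2).
#' @export
fit_mvee <- function(points, tolerance = 1e-4, max_iter = 10000L) {
  P <- as.matrix(points)
  if (ncol(P) != 3L) stop("fit_mvee: points must be an n x 3 matrix")
  if (!all(is.finite(P))) stop("fit_mvee: points must be finite")
  n <- nrow(P)
  if (n < 4L) stop("fit_mvee: at least 4 points are required")
  # affine-rank check: degenerate (coplanar / collinear) sets have no
  # finite-volume enclosing ellipsoid
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr), nu = 0, nv = 0)$d
  rel <- sv / max(sv[1], .Machine$double.eps)
  rank <- sum(rel > 1e-9)
  if (rank < 3L) {
    stop(sprintf(
      "fit_mvee: degenerate point set (affine rank %d < 3); points span only %d dimension(s)",
      rank, rank
    ))
  }

  d <- 3L
  # Core-set outer loop: the MVEE is determined by at most d(d+3)/2 contact
  # points on the convex hull, so iterate on a small working subset and
  # pull in violators until every point satisfies the containment bound.
  # Initial subset: extreme points along a fixed direction set.
  dirs <- rbind(diag(3), mvee_fib_directions(10))
  idx <- unique(as.vector(apply(P %*% t(dirs), 2, function(v) {
    c(which.max(v), which.min(v))
  })))
  core_tol <- tolerance / 2
  for (round in 1:50) {
    # the working subset must itself span 3D; add the points farthest from
    # its affine span until it does
    repeat {
      sub <- P[idx, , drop = FALSE]
      ctr_s <- colMeans(sub)
      sv_s <- svd(sweep(sub, 2, ctr_s))
      if (sum(sv_s$d / max(sv_s$d[1], .Machine$double.eps) > 1e-9) >= 3L) break
      k <- sum(sv_s$d / max(sv_s$d[1], .Machine$double.eps) > 1e-9)
      resid <- sweep(P, 2, ctr_s)
      if (k > 0L) {
        B <- sv_s$v[, seq_len(k), drop = FALSE]
        resid <- resid - (resid %*% B) %*% t(B)
      }
      idx <- c(idx, which.max(rowSums(resid^2)))
    }
    core <- mvee_khachiyan(P[idx, , drop = FALSE], core_tol, max_iter)
    v <- sweep(P, 2, core$center)
    vals <- rowSums((v %*% core$M) * v)
    viol <- which(vals > 1 + tolerance)
    viol <- setdiff(viol, idx)
    if (length(viol) == 0L) break
    viol <- viol[order(vals[viol], decreasing = TRUE)]
    idx <- c(idx, utils::head(viol, 20L))
  }

  es <- eigen(d * core$S, symmetric = TRUE)
  semi <- sqrt(pmax(es$values, 0))
  if (any(semi <= 0)) stop("fit_mvee: degenerate fit (zero semi-axis)")
  ellipsoid3d(core$center, semi, es$vectors)
}

# Deterministic quasi-uniform directions on the sphere (Fibonacci lattice).
mvee_fib_directions <- function(n) {
  gold <- pi * (3 - sqrt(5))
  k <- seq_len(n)
  z <- 1 - 2 * (k - 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(gold * k), r * sin(gold * k), z)
}

# Khachiyan barycentric coordinate ascent with Wolfe-Atwood away steps on
# one point set; returns center, scatter S (so M = solve(S)/d) and weights.
mvee_khachiyan <- function(P, tolerance, max_iter) {
  n <- nrow(P)
  d <- 3L
  # stop slightly tighter so the lab-frame bound (p-c)' M (p-c) <= 1 + tol
  # holds: lifted bound (d+1)(1+eps) maps to 1 + eps*(d+1)/d
  eps_stop <- tolerance * d / (d + 1)
  Q <- cbind(P, 1)              # n x 4 lifted points
  u <- rep(1 / n, n)

  for (iter in seq_len(max_iter)) {
    X <- crossprod(Q, Q * u)    # 4x4 = t(Q) %*% diag(u) %*% Q
    m <- rowSums(Q * t(solve(X, t(Q))))   # q_i' X^{-1} q_i
    jp <- which.max(m)
    eps_plus <- m[jp] / (d + 1) - 1
    active <- which(u > 0)
    jm <- active[which.min(m[active])]
    eps_minus <- 1 - m[jm] / (d + 1)
    if (max(eps_plus, eps_minus) < eps_stop) break
    if (eps_plus >= eps_minus) {
      lam <- (m[jp] - d - 1) / ((d + 1) * (m[jp] - 1))
      u <- u * (1 - lam)
      u[jp] <- u[jp] + lam
    } else {
      lam <- (d + 1 - m[jm]) / ((d + 1) * (m[jm] - 1))
      lam <- min(lam, u[jm] / (1 - u[jm]))
      u <- u * (1 + lam)
      u[jm] <- u[jm] - lam
      u[u < 0] <- 0
    }
    u <- u / sum(u)
  }

  center <- drop(crossprod(P, u))
  S <- crossprod(P, P * u) - tcrossprod(center)
  M <- solve(S) / d
  list(center = center, S = S, M = M, u = u)
}

#' Principal-axis endpoints of a spindle (or cortex) ellipsoid
#'
#' Derives the six points that define the spindle's length, width and height
#' axes: the endpoints of the three principal axes of the fitted ellipsoid.
#' Poles are the endpoints of the longest (length) axis; the reported
#' spindle length and width readouts are the full axis lengths `2a` and `2b`.
#'
#' @param ellipsoid an [ellipsoid3d()] object.
#' @return A `"spindle_axes"` object; see [spindle_axes()].
#' @export
principal_axes_endpoints <- function(ellipsoid) {
  stopifnot(inherits(ellipsoid, "ellipsoid3d"))
  ctr <- ellipsoid$center
  ax <- ellipsoid$semi_axes
  Q <- ellipsoid$orientation
  spindle_axes(
    pole1   = ctr + ax[1] * Q[, 1], pole2   = ctr - ax[1] * Q[, 1],
    width1  = ctr + ax[2] * Q[, 2], width2  = ctr - ax[2] * Q[, 2],
    height1 = ctr + ax[3] * Q[, 3], height2 = ctr - ax[3] * Q[, 3]
  )
}

#' Spindle principal axes
#'
#' Container for the six principal-axis endpoints (two poles on the length
#' axis, two width-axis endpoints, two height-axis endpoints) plus the
#' centroid. The centroid must be the common midpoint of all three endpoint
#' pairs and the three axis directions must be mutually orthogonal.
#'
#' @param pole1,pole2 length-axis endpoints (numeric length-3, micrometres).
#' @param width1,width2 width-axis endpoints.
#' @param height1,height2 height-axis endpoints.
#' @return An object of class `"spindle_axes"` with the six endpoints,
#'   `centroid`, and readouts `length_um`, `width_um`, `height_um`.
#' @export
spindle_axes <- function(pole1, pole2, width1, width2, height1, height2) {
  pts <- list(pole1 = as.numeric(pole1), pole2 = as.numeric(pole2),
              width1 = as.numeric(width1), width2 = as.numeric(width2),
              height1 = as.numeric(height1), height2 = as.numeric(height2))
  if (any(vapply(pts, length, 1L) != 3L)) {
    stop("spindle_axes: endpoints must be length-3 numeric vectors")
  }
  mids <- list((pts$pole1 + pts$pole2) / 2,
               (pts$width1 + pts$width2) / 2,
               (pts$height1 + pts$height2) / 2)
  scale <- max(1, max(abs(unlist(pts))))
  if (max(abs(mids[[1]] - mids[[2]])) > 1e-6 * scale ||
      max(abs(mids[[1]] - mids[[3]])) > 1e-6 * scale) {
    stop("spindle_axes: endpoint pairs do not share a common midpoint")
  }
  dirs <- cbind(pts$pole1 - pts$pole2, pts$width1 - pts$width2,
                pts$height1 - pts$height2)
  dirs <- sweep(dirs, 2, sqrt(colSums(dirs^2)), "/")
  G <- crossprod(dirs)
  if (max(abs(G - diag(3))) > 1e-5) {
    stop("spindle_axes: axis directions are not mutually orthogonal")
  }
  structure(
    c(pts, list(
      centroid = mids[[1]],
      length_um = sqrt(sum((pts$pole1 - pts$pole2)^2)),
      width_um = sqrt(sum((pts$width1 - pts$width2)^2)),
      height_um = sqrt(sum((pts$height1 - pts$height2)^2))
    )),
    class = "spindle_axes"
  )
}

#' @export
print.spindle_axes <- function(x, ...) {
  cat("Spindle principal axes\n")
  cat(sprintf("  length %.3f um, width %.3f um, height %.3f um\n",
              x$length_um, x$width_um, x$height_um))
  cat("  centroid (um):", paste(signif(x$centroid, 6), collapse = ", "), "\n")
  invisible(x)
}

# Unit direction matrix (columns: length, width, height) of a spindle_axes.
axes_triad <- function(axes) {
  dirs <- cbind(axes$pole1 - axes$pole2,
                axes$width1 - axes$width2,
                axes$height1 - axes$height2)
  sweep(dirs, 2, sqrt(colSums(dirs^2)), "/")
}
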