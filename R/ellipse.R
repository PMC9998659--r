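#' Ellipse in 2D
#'
#' @param center numeric length-2 center (pixels or micrometres).
#' @param semi_axes numeric length-2 `(A, B)`; stored with `A >= B`.
#' @param angle_deg major-axis angle in degrees, normalised to `(-90, 90]`.
#' @return An object of class `"ellipse2d"`.
#' @export
ellipse2d <- function(center, semi_axes, angle_deg = 0) {
  center <- unname(as.numeric(center))
  semi_axes <- unname(as.numeric(semi_axes))
  angle_deg <- unname(as.numeric(angle_deg))
  stopifnot(length(center) == 2L, length(semi_axes) == 2L)
  if (any(semi_axes <= 0) || any(!is.finite(semi_axes))) {
    stop("ellipse2d: semi-axes must be strictly positive")
  }
  if (semi_axes[1] < semi_axes[2]) {
    semi_axes <- rev(semi_axes)
    angle_deg <- angle_deg + 90
  }
  angle_deg <- ((angle_deg + 90) %% 180) - 90
  if (angle_deg == -90) angle_deg <- 90
  structure(list(center = center, semi_axes = semi_axes,
                 angle_deg = angle_deg),
            class = "ellipse2d")
}

#' @export
print.ellipse2d <- function(x, ...) {
  cat(sprintf("2D ellipse: center (%.3f, %.3f), semi-axes (%.3f, %.3f), angle %.2f deg\n",
              x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
              x$angle_deg))
  invisible(x)
}

#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to boundary points by the direct conic least-squares
#' method with the ellipse-specific constraint `4ac - b^2 = 1`
#' (Fitzgibbon et al.), using the numerically stable partitioned
#' formulation of Halir & Flusser. Used as the final step of the classical
#' spindle segmentation pipelines to summarise the smoothed boundary.
#'
#' @param boundary numeric matrix (n x 2) of boundary points, n >= 5.
#' @return An [ellipse2d()] object with geometric parameters.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 50)
#' fit_ellipse_2d(cbind(5 * cos(th), 2 * sin(th)))
#' @export
fit_ellipse_2d <- function(boundary) {
  B <- as.matrix(boundary)
  if (ncol(B) != 2L) stop("fit_ellipse_2d: boundary must be an n x 2 matrix")
  B <- B[stats::complete.cases(B), , drop = FALSE]
  B <- unique(B)
  if (nrow(B) < 5L) {
    stop("fit_ellipse_2d: degenerate geometry - at least 5 distinct points required")
  }
  # center/scale for conditioning
  mu <- colMeans(B)
  sc <- max(apply(B, 2, stats::sd))
  if (!is.finite(sc) || sc <= 0) {
    stop("fit_ellipse_2d: degenerate geometry - points are coincident")
  }
  x <- (B[, 1] - mu[1]) / sc
  y <- (B[, 2] - mu[2]) / sc

  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Cinv <- matrix(c(0, 0, 0.5, 0, -1, 0, 0.5, 0, 0), 3, 3)
  T2 <- tryCatch(-solve(S3, t(S2)), error = function(e) {
    stop("fit_ellipse_2d: degenerate geometry - singular scatter matrix")
  })
  M <- Cinv %*% (S1 + S2 %*% T2)
  ev <- eigen(M)
  # pick the eigenvector satisfying the ellipse constraint 4ac - b^2 > 0
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0 & abs(Im(ev$values)) < 1e-8)
  if (length(ok) == 0L) {
    stop("fit_ellipse_2d: degenerate geometry - fitted conic is not an ellipse")
  }
  a1 <- V[, ok[1]]
  coefs <- c(a1, drop(T2 %*% a1))   # (a, b, c, d, e, f) in scaled coords

  # back to original coordinates: substitute x -> (x - mu1)/sc etc.
  A <- coefs[1]; Bc <- coefs[2]; Cc <- coefs[3]
  Dd <- coefs[4]; Ee <- coefs[5]; Ff <- coefs[6]
  a0 <- A / sc^2
  b0 <- Bc / sc^2
  c0 <- Cc / sc^2
  d0 <- Dd / sc - 2 * A * mu[1] / sc^2 - Bc * mu[2] / sc^2
  e0 <- Ee / sc - 2 * Cc * mu[2] / sc^2 - Bc * mu[1] / sc^2
  f0 <- Ff + A * mu[1]^2 / sc^2 + Cc * mu[2]^2 / sc^2 +
    Bc * mu[1] * mu[2] / sc^2 - Dd * mu[1] / sc - Ee * mu[2] / sc
  conic_to_ellipse(c(a0, b0, c0, d0, e0, f0))
}

# Convert conic coefficients (a,b,c,d,e,f) of
# a x^2 + b xy + c y^2 + d x + e y + f = 0 to geometric parameters.
conic_to_ellipse <- function(k) {
  # overall conic scale is arbitrary; normalise the sign so the quadratic
  # part is positive definite (a + c > 0 when 4ac - b^2 > 0)
  if (k[1] + k[3] < 0) k <- -k
  a <- k[1]; b <- k[2]; cc <- k[3]; d <- k[4]; e <- k[5]; f <- k[6]
  den <- 4 * a * cc - b^2
  if (den <= 0) stop("conic_to_ellipse: conic is not an ellipse")
  x0 <- (b * e - 2 * cc * d) / den
  y0 <- (b * d - 2 * a * e) / den
  # value of the quadratic form at the center
  fc <- a * x0^2 + b * x0 * y0 + cc * y0^2 + d * x0 + e * y0 + f
  num <- -fc
  if (num <= 0) stop("conic_to_ellipse: degenerate ellipse")
  # eigenvalues of [[a, b/2], [b/2, c]]
  tr <- a + cc
  dif <- sqrt((a - cc)^2 + b^2)
  l1 <- (tr - dif) / 2   # smaller eigenvalue -> major axis
  l2 <- (tr + dif) / 2
  Amaj <- sqrt(num / l1)
  Bmin <- sqrt(num / l2)
  # major-axis direction = eigenvector of the smaller eigenvalue l1
  if (abs(b) > 1e-14 * max(abs(a), abs(cc), 1)) {
    v <- c(b / 2, l1 - a)
    angle <- atan2(v[2], v[1]) * 180 / pi
  } else {
    angle <- if (a <= cc) 0 else 90
  }
  ellipse2d(c(x0, y0), c(Amaj, Bmin), angle)
}

#' Ellipse eccentricity
#'
#' `sqrt(1 - B^2/A^2)`: 0 is a perfect circle, values approaching 1 a line.
#' Used as the cortex-roundness readout (mitotic cells are nearly but not
#' exactly circular) and to quantify fluorescent-foci shape.
#'
#' @param ellipse an [ellipse2d()] object.
#' @return Scalar in `[0, 1)`.
#' @examples
#' eccentricity(ellipse2d(c(0, 0), c(2, 1)))  # sqrt(3)/2
#' @export
eccentricity <- function(ellipse) {
  stopifnot(inherits(ellipse, "ellipse2d"))
  A <- ellipse$semi_axes[1]
  B <- ellipse$semi_axes[2]
  sqrt(max(0, 1 - B^2 / A^2))
}
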