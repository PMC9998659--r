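# Classical (non-learned) annotation pipelines, candidate filtering and
# centroid linking. Matrices are [row = y, col = x]; candidates use 1-based
# pixel indices.

normalize01 <- function(image) {
  image <- as.matrix(image)
  rng <- range(image)
  if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1]) else image * 0
}

#' Segmentation candidate
#'
#' A candidate object mask with its confidence score, tight bounding box
#' and pixel area, the unit that conditional filtering and centroid
#' tracking operate on. Classical pipelines emit candidates with score
#' 1.0 so the same downstream filtering applies to scored (learned) and
#' unscored (classical) masks.
#'
#' @param mask 2D binary matrix.
#' @param score confidence in `[0, 1]`.
#' @param class_name free-text class label.
#' @return An object of class `"segmentation_candidate"` with `mask`,
#'   `score`, `bbox` (`x_min`, `y_min`, `x_max`, `y_max`, 1-based, tight),
#'   `area_px`, `class_name` and `centroid` (bbox center, `(x, y)`).
#' @export
segmentation_candidate <- function(mask, score = 1.0, class_name = "object") {
  mask <- as.matrix(mask) > 0
  if (!any(mask)) stop("segmentation_candidate: mask is empty")
  if (score < 0 || score > 1) stop("segmentation_candidate: score must be in [0, 1]")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  bbox <- c(x_min = cols[1], y_min = rows[1], x_max = cols[2], y_max = rows[2])
  structure(list(mask = mask, score = score, bbox = bbox,
                 area_px = sum(mask), class_name = class_name,
                 centroid = c(x = mean(cols), y = mean(rows))),
            class = "segmentation_candidate")
}

#' @export
print.segmentation_candidate <- function(x, ...) {
  cat(sprintf("Candidate '%s': score %.3f, area %d px, bbox x[%d,%d] y[%d,%d]\n",
              x$class_name, x$score, x$area_px,
              x$bbox["x_min"], x$bbox["x_max"], x$bbox["y_min"], x$bbox["y_max"]))
  invisible(x)
}

# --- geometry helpers ------------------------------------------------------

# Ordered outer boundary (row, col matrix) of the largest-label object.
trace_boundary <- function(mask) {
  oc <- EBImage::ocontour(EBImage::bwlabel(mask))
  if (length(oc) == 0L) stop("trace_boundary: no object found")
  # pick the longest contour; EBImage indexes the first array dimension as
  # x, so with [row, col] matrices column 1 is the row index (0-based)
  b <- oc[[which.max(vapply(oc, nrow, 0L))]]
  cbind(row = b[, 1] + 1, col = b[, 2] + 1)
}

# Savitzky-Golay smoothing of a closed boundary: the row and column series
# are treated as two periodic 1D signals.
smooth_boundary <- function(boundary, window = 15L, order = 3L) {
  n <- nrow(boundary)
  if (n < 5L) return(boundary)
  window <- min(window, if (n %% 2L == 1L) n else n - 1L)
  if (window %% 2L == 0L) window <- window - 1L
  if (window <= order) return(boundary)
  half <- (window - 1L) %/% 2L
  wrap <- function(v) {
    ext <- c(utils::tail(v, half), v, utils::head(v, half))
    sm <- signal::sgolayfilt(ext, p = order, n = window)
    sm[(half + 1):(half + n)]
  }
  cbind(row = wrap(boundary[, 1]), col = wrap(boundary[, 2]))
}

# Even-odd scanline rasterisation of a closed polygon given in (row, col).
fill_polygon <- function(poly, dim) {
  out <- matrix(FALSE, dim[1], dim[2])
  yr <- poly[, 1]
  xc <- poly[, 2]
  n <- length(yr)
  nxt <- c(2:n, 1)
  for (r in max(1L, floor(min(yr))):min(dim[1], ceiling(max(yr)))) {
    y <- r
    y1 <- yr; y2 <- yr[nxt]
    crosses <- (y1 <= y & y2 > y) | (y2 <= y & y1 > y)
    if (!any(crosses)) next
    xs <- xc[crosses] + (y - y1[crosses]) / (y2[crosses] - y1[crosses]) *
      (xc[nxt][crosses] - xc[crosses])
    xs <- sort(xs)
    for (k in seq(1, length(xs) - 1, by = 2)) {
      c1 <- max(1L, ceiling(xs[k]))
      c2 <- min(dim[2], floor(xs[k + 1]))
      if (c1 <= c2) out[r, c1:c2] <- TRUE
    }
  }
  out
}

# Remove 8-connected components touching the image border by flooding
# inward from border foreground pixels (8-connected dilation within mask).
clear_border_objects <- function(mask) {
  seed <- matrix(FALSE, nrow(mask), ncol(mask))
  seed[1, ] <- mask[1, ]; seed[nrow(mask), ] <- mask[nrow(mask), ]
  seed[, 1] <- mask[, 1]; seed[, ncol(mask)] <- mask[, ncol(mask)]
  if (!any(seed)) return(mask)
  brush <- matrix(1, 3, 3)
  repeat {
    grown <- (EBImage::filter2(seed * 1, brush, boundary = 0) > 0.5) & mask
    if (identical(grown, seed)) break
    seed <- grown
  }
  mask & !seed
}

# --- annotation pipelines --------------------------------------------------

#' Segment the metaphase chromosome plate (Otsu pipeline)
#'
#' Classical pipeline for fluorescently labelled chromosomes: median
#' filter, Otsu two-class thresholding, removal of 8-connected components
#' touching the image border, then boundary extraction, periodic
#' Savitzky-Golay contour smoothing and refilling of the largest remaining
#' object.
#'
#' @param image 2D single-channel intensity matrix.
#' @param median_size odd median-filter window (default 5).
#' @param savgol_window,savgol_order Savitzky-Golay window (odd, default
#'   15) and polynomial order (default 3; must be < window).
#' @return A [segmentation_candidate()] (score fixed at 1.0, class
#'   `"chromosome"`).
#' @export
segment_chromosomes <- function(image, median_size = 5L, savgol_window = 15L,
                                savgol_order = 3L) {
  if (savgol_order >= savgol_window) {
    stop("segment_chromosomes: savgol_order must be smaller than savgol_window")
  }
  img <- normalize01(image)
  med <- EBImage::medianFilter(img, size = max(1L, median_size %/% 2L))
  thr <- EBImage::otsu(EBImage::Image(med), range = c(0, 1))
  bin <- med > thr
  bin <- clear_border_objects(bin)
  if (!any(bin)) {
    stop("segment_chromosomes: empty result - no object survives thresholding and border clearing")
  }
  lab <- EBImage::bwlabel(bin)
  sizes <- tabulate(lab[lab > 0])
  main <- lab == which.max(sizes)
  bnd <- trace_boundary(main)
  sm <- smooth_boundary(bnd, savgol_window, savgol_order)
  filled <- fill_polygon(sm, dim(img))
  if (!any(filled)) filled <- main
  segmentation_candidate(filled, score = 1.0, class_name = "chromosome")
}

#' Segment a dye-labelled spindle (adaptive threshold + convex hull)
#'
#' Classical pipeline for SiR-tubulin-like spindle images: median filter,
#' adaptive (local-mean) threshold, one round of 3x3 disc dilation and
#' erosion to remove artifacts, convex hull of all retained foreground
#' (joining the two spindle halves), periodic Savitzky-Golay boundary
#' smoothing and a direct least-squares ellipse fit of the hull boundary.
#'
#' @param image 2D intensity matrix.
#' @param median_size length-2 median window (default `c(20, 20)`; applied
#'   as a disc of radius `max(median_size) %/% 2`).
#' @param adaptive_block_px odd local-mean neighbourhood (default 51).
#' @param offset threshold offset above the local mean, on the normalised
#'   intensity scale (default 0.02).
#' @return A list with `candidate` (a [segmentation_candidate()], class
#'   `"spindle"`, hull mask) and `ellipse` (an [ellipse2d()]).
#' @export
segment_spindle_threshold <- function(image, median_size = c(20L, 20L),
                                      adaptive_block_px = 51L,
                                      offset = 0.02) {
  img <- normalize01(image)
  med <- EBImage::medianFilter(img, size = max(1L, max(median_size) %/% 2L))
  b <- min(adaptive_block_px, 2L * (min(dim(img)) %/% 2L) - 1L)
  box <- matrix(1 / (b * b), b, b)
  loc <- EBImage::filter2(med, box, boundary = "replicate")
  bin <- med > (loc + offset)
  brush <- EBImage::makeBrush(3, shape = "disc")
  bin <- EBImage::erode(EBImage::dilate(bin, brush), brush) > 0
  if (!any(bin)) {
    stop("segment_spindle_threshold: degenerate geometry - nothing above the adaptive threshold")
  }
  fg <- which(bin, arr.ind = TRUE)            # (row, col)
  hull_idx <- grDevices::chull(fg[, 2], fg[, 1])
  hull <- fg[hull_idx, , drop = FALSE]
  if (nrow(hull) < 3L) {
    stop("segment_spindle_threshold: degenerate geometry - foreground is collinear")
  }
  hull_mask <- fill_polygon(hull, dim(img)) | bin
  bnd <- trace_boundary(hull_mask)
  sm <- smooth_boundary(bnd)
  if (nrow(unique(sm)) < 5L) {
    stop("segment_spindle_threshold: degenerate geometry - fewer than 5 boundary points")
  }
  ell <- fit_ellipse_2d(cbind(sm[, 2], sm[, 1]))   # (x, y) = (col, row)
  list(candidate = segmentation_candidate(hull_mask, 1.0, "spindle"),
       ellipse = ell)
}

#' Segment a spindle with an inverse (outward) active contour
#'
#' Classical pipeline for mCherry-tubulin-like spindle images where
#' thresholding is unreliable: Gaussian smoothing, image gradient
#' magnitude as the edge map, and an active contour seeded on the
#' chromosome-plate boundary and propagated outward ("inverse snake",
#' from the spindle center towards its outer boundary, avoiding
#' cytoplasmic noise). The contour moves along its outward radial normals
#' with a speed that vanishes where the edge response is strong, under
#' elastic and rigidity regularisation applied implicitly each step.
#'
#' @param image 2D intensity matrix.
#' @param chromosome_mask non-empty binary seed mask (typically from
#'   [segment_chromosomes()]).
#' @param snake_params list overriding any of `alpha_elastic` (0.02),
#'   `beta_rigid` (0.01), `gamma_step` (0.8 px), `iterations` (250),
#'   `n_points` (120), `sigma` (2, Gaussian pre-smoothing), `edge_stop`
#'   (0.6, edge response at which motion stops, relative to the maximum).
#' @return A list with `candidate` (class `"spindle"`) and `ellipse`.
#' @export
segment_spindle_snake <- function(image, chromosome_mask,
                                  snake_params = list()) {
  p <- utils::modifyList(
    list(alpha_elastic = 0.02, beta_rigid = 0.01, gamma_step = 0.8,
         iterations = 250L, n_points = 120L, sigma = 2, edge_stop = 0.6),
    snake_params)
  mask <- as.matrix(chromosome_mask) > 0
  if (!any(mask)) stop("segment_spindle_snake: seed error - chromosome mask is empty")
  img <- normalize01(image)
  sm <- EBImage::gblur(img, sigma = p$sigma)
  gx <- (cbind(sm[, -1], sm[, ncol(sm)]) - cbind(sm[, 1], sm[, -ncol(sm)])) / 2
  gy <- (rbind(sm[-1, ], sm[nrow(sm), ]) - rbind(sm[1, ], sm[-nrow(sm), ])) / 2
  edge <- sqrt(gx^2 + gy^2)
  edge <- edge / max(edge, .Machine$double.eps)

  bnd <- trace_boundary(mask)
  s <- resample_contour(bnd, p$n_points)        # (row, col), closed
  seed_area <- polygon_area(s)
  ctr <- colMeans(s)

  n <- p$n_points
  A2 <- circulant_diff(n, c(1, -2, 1))
  A4 <- circulant_diff(n, c(1, -4, 6, -4, 1))
  # internal energy: -alpha * second difference (elasticity, PSD) plus
  # beta * fourth difference (rigidity, PSD), applied implicitly
  M <- diag(n) + p$gamma_step * (p$alpha_elastic * (-A2) + p$beta_rigid * A4)
  Minv <- solve(M)

  for (it in seq_len(p$iterations)) {
    rad <- sweep(s, 2, ctr)
    nr <- sqrt(rowSums(rad^2))
    nr[nr == 0] <- 1
    normal <- rad / nr
    e <- bilinear_at(edge, s)
    speed <- pmax(0, 1 - e / p$edge_stop)
    step <- p$gamma_step * speed
    s_new <- Minv %*% (s + step * normal)
    s_new[, 1] <- pmin(pmax(s_new[, 1], 1), nrow(img))
    s_new[, 2] <- pmin(pmax(s_new[, 2], 1), ncol(img))
    moved <- max(abs(s_new - s))
    s <- s_new
    ctr <- colMeans(s)
    if (moved < 1e-3) break
  }
  if (polygon_area(s) < seed_area) {
    stop("segment_spindle_snake: convergence error - contour collapsed below the seed area")
  }
  sb <- smooth_boundary(s)
  ell <- fit_ellipse_2d(cbind(sb[, 2], sb[, 1]))
  cand_mask <- fill_polygon(sb, dim(img))
  list(candidate = segmentation_candidate(cand_mask, 1.0, "spindle"),
       ellipse = ell)
}

# Uniform arc-length resampling of a closed contour to n points.
resample_contour <- function(boundary, n) {
  b <- rbind(boundary, boundary[1, ])
  seg <- sqrt(rowSums(diff(b)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  at <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  r <- stats::approx(cum, b[, 1], xout = at)$y
  cc <- stats::approx(cum, b[, 2], xout = at)$y
  cbind(row = r, col = cc)
}

polygon_area <- function(poly) {
  x <- poly[, 2]; y <- poly[, 1]
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Circulant matrix applying the given centered difference stencil.
circulant_diff <- function(n, stencil) {
  k <- length(stencil)
  half <- (k - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (s in seq_len(k)) {
      j <- ((i - 1L + s - 1L - half) %% n) + 1L
      M[i, j] <- M[i, j] + stencil[s]
    }
  }
  M
}

bilinear_at <- function(img, pts) {
  r <- pmin(pmax(pts[, 1], 1), nrow(img))
  cc <- pmin(pmax(pts[, 2], 1), ncol(img))
  r0 <- pmin(floor(r), nrow(img) - 1L)
  c0 <- pmin(floor(cc), ncol(img) - 1L)
  fr <- r - r0
  fc <- cc - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# --- Stage-3 filtering and linking ----------------------------------------

#' Filtering rules for detected candidates
#'
#' @param min_score minimum confidence in `[0, 1]` (default 0.9, the
#'   standard detection threshold).
#' @param min_area_px,max_area_px admissible pixel-area range
#'   (`min < max`).
#' @param border_margin_px minimum distance (pixels) between the bounding
#'   box and every canvas edge (default 0).
#' @return An object of class `"filter_rules"`.
#' @export
filter_rules <- function(min_score = 0.9, min_area_px = 1L,
                         max_area_px = .Machine$integer.max,
                         border_margin_px = 0L) {
  if (min_score < 0 || min_score > 1) stop("filter_rules: min_score must be in [0, 1]")
  if (min_area_px >= max_area_px) stop("filter_rules: min_area_px must be < max_area_px")
  if (border_margin_px < 0) stop("filter_rules: border margin must be >= 0")
  structure(list(min_score = min_score, min_area_px = min_area_px,
                 max_area_px = max_area_px,
                 border_margin_px = border_margin_px),
            class = "filter_rules")
}

#' Conditional filtering of segmentation candidates
#'
#' Retains only candidates that pass all rules: confidence score at least
#' `min_score`, area within `[min_area_px, max_area_px]`, and bounding box
#' at least `border_margin_px` away from every canvas edge (objects close
#' to the border are usually truncated and would corrupt the 3D fit).
#' Order is preserved and the operation is idempotent.
#'
#' @param candidates list of [segmentation_candidate()] objects.
#' @param rules a [filter_rules()].
#' @param canvas integer `(rows, cols)` of the shared image canvas.
#' @return The retained sublist (possibly empty).
#' @export
conditional_filter <- function(candidates, rules, canvas) {
  stopifnot(inherits(rules, "filter_rules"))
  keep <- vapply(candidates, function(cd) {
    bb <- cd$bbox
    cd$score >= rules$min_score &&
      cd$area_px >= rules$min_area_px &&
      cd$area_px <= rules$max_area_px &&
      (bb["x_min"] - 1L) >= rules$border_margin_px &&
      (bb["y_min"] - 1L) >= rules$border_margin_px &&
      (canvas[2] - bb["x_max"]) >= rules$border_margin_px &&
      (canvas[1] - bb["y_max"]) >= rules$border_margin_px
  }, TRUE)
  candidates[keep]
}

#' Link one object through time by nearest bounding-box centroid
#'
#' Single-object k-nearest-neighbour (k = 1) linking: frame 1 selects the
#' highest-score candidate (ties: lowest index); each later frame selects
#' the candidate whose bounding-box centroid is nearest (Euclidean) to the
#' previously selected centroid, breaking distance ties by higher score
#' then lower index. Frames with no candidates are flagged as gaps and
#' the last known centroid is carried forward for matching.
#'
#' @param candidates_per_frame list (one element per frame) of candidate
#'   lists; frame 1 must be non-empty.
#' @return A list with `selected` (per-frame candidate or `NULL`),
#'   `index` (per-frame chosen index, `NA` on gaps), `gap` (logical) and
#'   `centroids` (matrix of the tracked centroid per frame).
#' @export
track_centroids <- function(candidates_per_frame) {
  n <- length(candidates_per_frame)
  if (n == 0L || length(candidates_per_frame[[1]]) == 0L) {
    stop("track_centroids: initialization error - frame 1 has no candidates")
  }
  selected <- vector("list", n)
  index <- rep(NA_integer_, n)
  gap <- logical(n)
  centroids <- matrix(NA_real_, n, 2)
  first <- candidates_per_frame[[1]]
  scores <- vapply(first, function(cd) cd$score, 0)
  index[1] <- which.max(scores)
  selected[[1]] <- first[[index[1]]]
  ref <- selected[[1]]$centroid
  centroids[1, ] <- ref
  for (t in seq_len(n)[-1]) {
    cands <- candidates_per_frame[[t]]
    if (length(cands) == 0L) {
      gap[t] <- TRUE
      centroids[t, ] <- ref    # carried for matching
      next
    }
    cents <- t(vapply(cands, function(cd) cd$centroid, numeric(2)))
    d <- sqrt(rowSums(sweep(cents, 2, ref)^2))
    best <- which(d == min(d))
    if (length(best) > 1L) {
      sc <- vapply(cands[best], function(cd) cd$score, 0)
      best <- best[order(-sc, best)][1]
    }
    index[t] <- best
    selected[[t]] <- cands[[best]]
    ref <- cands[[best]]$centroid
    centroids[t, ] <- ref
  }
  list(selected = selected, index = index, gap = gap, centroids = centroids)
}
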