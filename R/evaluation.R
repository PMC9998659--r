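#' Intersection over union of two binary masks
#'
#' `|A intersect B| / |A union B|`; defined as 1 when both masks are empty
#' (perfect agreement on "nothing there").
#'
#' @param mask_a,mask_b 2D binary matrices of equal shape.
#' @return Scalar in `[0, 1]`.
#' @export
iou <- function(mask_a, mask_b) {
  a <- as.matrix(mask_a) > 0
  b <- as.matrix(mask_b) > 0
  if (!all(dim(a) == dim(b))) stop("iou: mask shapes differ")
  un <- sum(a | b)
  if (un == 0L) return(1)
  sum(a & b) / un
}

#' Average precision of scored mask predictions
#'
#' Sweeps predictions in descending score order, greedily matching each to
#' an unconsumed ground-truth mask when their IoU reaches the threshold,
#' and accumulates the all-points precision-recall sum
#' `AP = sum_n (R_n - R_(n-1)) * P_n`.
#'
#' @param predictions list of [segmentation_candidate()] objects (scored).
#' @param truths list of 2D binary ground-truth masks.
#' @param iou_threshold minimum IoU for a match (default 0.5).
#' @return Scalar AP in `[0, 1]`.
#' @export
average_precision <- function(predictions, truths, iou_threshold = 0.5) {
  if (length(truths) == 0L) {
    stop("average_precision: undefined metric - no ground-truth masks")
  }
  if (length(predictions) == 0L) return(0)
  scores <- vapply(predictions, function(p) p$score, 0)
  ord <- order(scores, decreasing = TRUE)
  used <- logical(length(truths))
  tp <- numeric(length(predictions))
  for (k in seq_along(ord)) {
    p <- predictions[[ord[k]]]
    ious <- vapply(seq_along(truths), function(j) {
      if (used[j]) -1 else iou(p$mask, truths[[j]])
    }, 0)
    j <- which.max(ious)
    if (ious[j] >= iou_threshold) {
      used[j] <- TRUE
      tp[k] <- 1
    }
  }
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / length(truths)
  sum(diff(c(0, recall)) * precision)
}

#' Pixelwise correlation between automated and manual masks
#'
#' Pearson correlation of the flattened binary masks (equivalently the phi
#' coefficient of the 2x2 pixel contingency table), quantifying
#' human-versus-automated segmentation agreement.
#'
#' @param auto,manual 2D binary matrices of equal shape; neither may be
#'   constant (all fore- or all background), since the correlation is then
#'   undefined.
#' @return Scalar in `[-1, 1]`.
#' @export
mask_correlation <- function(auto, manual) {
  a <- as.numeric(as.matrix(auto) > 0)
  m <- as.numeric(as.matrix(manual) > 0)
  if (length(a) != length(m)) stop("mask_correlation: mask shapes differ")
  if (stats::sd(a) == 0 || stats::sd(m) == 0) {
    stop("mask_correlation: undefined metric - a mask is constant")
  }
  stats::cor(a, m)
}

#' Spindle / chromosome-plate perpendicularity
#'
#' Acute angle between the spindle-fit major axis and the chromosome-plate
#' major axis. In a healthy metaphase the plate is perpendicular to the
#' spindle axis, so values near 90 degrees are a segmentation quality
#' check.
#'
#' @param spindle_ellipse,chromosome_ellipse [ellipse2d()] objects.
#' @return Angle in degrees, `[0, 90]`. Warns when either ellipse is
#'   nearly circular (eccentricity < 0.1), where the major-axis
#'   orientation is poorly defined.
#' @export
perpendicularity <- function(spindle_ellipse, chromosome_ellipse) {
  stopifnot(inherits(spindle_ellipse, "ellipse2d"),
            inherits(chromosome_ellipse, "ellipse2d"))
  if (eccentricity(spindle_ellipse) < 0.1 ||
      eccentricity(chromosome_ellipse) < 0.1) {
    warning("perpendicularity: near-circular ellipse, orientation is poorly defined")
  }
  d <- abs(spindle_ellipse$angle_deg - chromosome_ellipse$angle_deg) %% 180
  min(d, 180 - d)
}

#' Manual error-classification taxonomy
#'
#' Category constants for manual reporting of segmentation errors:
#' under-segmentation (minor/major), over-segmentation (minor/major) and
#' multiple-objects-with-artifacts. Documentation constants only; no
#' automatic classifier is provided.
#'
#' @format Named character vector of length 5.
#' @export
segmentation_error_classes <- c(
  u_minor = "U-Minor",
  u_major = "U-Major",
  o_minor = "O-Minor",
  o_major = "O-Major",
  mo = "MO"
)
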