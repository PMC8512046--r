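.check_same_dim <- function(a, b) {
  if (nrow(a) != nrow(b) || ncol(a) != ncol(b))
    stop("label maps have different dimensions (", nrow(a), "x", ncol(a),
         " vs ", nrow(b), "x", ncol(b), ")", call. = FALSE)
}

# Chebyshev dilation of a logical mask by radius eps (square structuring
# element of side 2*eps + 1), done with integer shifts.
.dilate_chebyshev <- function(mask, eps) {
  if (eps == 0L) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (dr in -eps:eps) for (dc in -eps:eps) {
    r1 <- max(1L, 1L + dr):min(h, h + dr)
    c1 <- max(1L, 1L + dc):min(w, w + dc)
    out[r1, c1] <- out[r1, c1] | mask[r1 - dr, c1 - dc, drop = FALSE]
  }
  out
}

#' Boundary Recall of a predicted boundary map
#'
#' Fraction of ground-truth boundary pixels that lie within Chebyshev
#' distance `epsilon` of some predicted boundary pixel. Ground-truth
#' boundaries are derived from the label map by the 4-neighbor rule and
#' thinned to one side of each interface ([boundary_pixels_thin()]) so
#' the denominator counts each interface once. Returns 1 when the ground
#' truth has no boundary pixels.
#'
#' @param pred logical predicted boundary matrix (e.g. from
#'   [extract_boundaries()]).
#' @param gt integer ground-truth label matrix (same dimensions), or a
#'   list of such matrices (multiple annotations; see `gt_mode`).
#' @param epsilon tolerance in pixels (>= 0, default 2).
#' @param gt_mode with multiple annotations: `"average"` (default) or
#'   `"max"` over per-annotation recalls.
#' @return Boundary Recall in \[0, 1\].
#' @export
boundary_recall <- function(pred, gt, epsilon = 2, gt_mode = c("average",
                                                               "max")) {
  gt_mode <- match.arg(gt_mode)
  if (!is.numeric(epsilon) || epsilon < 0)
    stop("epsilon must be >= 0", call. = FALSE)
  if (is.list(gt)) {
    vals <- vapply(gt, function(g) boundary_recall(pred, g, epsilon),
                   numeric(1))
    return(if (gt_mode == "average") mean(vals) else max(vals))
  }
  pred <- unclass(pred); gt <- unclass(gt)
  .check_same_dim(pred, gt)
  gt_b <- boundary_pixels_thin(gt)
  n_gt <- sum(gt_b)
  if (n_gt == 0L) return(1)
  hit <- .dilate_chebyshev(pred, as.integer(floor(epsilon)))
  sum(gt_b & hit) / n_gt
}

#' Achievable Segmentation Accuracy
#'
#' Upper bound on the accuracy obtainable by labeling every superpixel
#' with its best-overlapping ground-truth region: the sum over
#' superpixels of their maximum pixel overlap with any single region,
#' divided by the total pixel count.
#'
#' @param map integer superpixel label matrix.
#' @param gt integer ground-truth label matrix (same dimensions), or a
#'   list of them.
#' @param gt_mode with multiple annotations: `"average"` or `"max"`.
#' @return ASA in \[0, 1\].
#' @export
achievable_segmentation_accuracy <- function(map, gt,
                                             gt_mode = c("average",
                                                         "max")) {
  gt_mode <- match.arg(gt_mode)
  if (is.list(gt)) {
    vals <- vapply(gt,
                   function(g) achievable_segmentation_accuracy(map, g),
                   numeric(1))
    return(if (gt_mode == "average") mean(vals) else max(vals))
  }
  map <- unclass(map); gt <- unclass(gt)
  .check_same_dim(map, gt)
  tab <- table(as.vector(map), as.vector(gt))
  sum(apply(tab, 1L, max)) / length(map)
}

#' Boundary Recall and ASA for a segmentation
#'
#' Convenience wrapper computing both metrics plus the superpixel count.
#'
#' @param map integer superpixel label matrix.
#' @param gt ground-truth label matrix or list of annotations.
#' @param epsilon Boundary Recall tolerance in pixels.
#' @param gt_mode annotation aggregation mode.
#' @return list with `br`, `asa`, `n_superpixels`.
#' @export
segmentation_metrics <- function(map, gt, epsilon = 2,
                                 gt_mode = c("average", "max")) {
  gt_mode <- match.arg(gt_mode)
  pred_b <- extract_boundaries(map)
  list(br = boundary_recall(pred_b, gt, epsilon, gt_mode),
       asa = achievable_segmentation_accuracy(map, gt, gt_mode),
       n_superpixels = length(unique(as.vector(unclass(map)))))
}
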