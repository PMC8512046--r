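# Nearest cell-center index along one axis (centers at (k-1)*R + R%/%2 + 1,
# k = 1..n); exact ties resolve to the lower index, clamped so remainder
# strips join the last cell.
.nearest_cell <- function(coord, R, n) {
  off <- R %/% 2L
  lo <- floor((coord - off - 1L) / R)
  hi <- lo + 1
  pick <- ifelse(abs(coord - (lo * R + off + 1L)) <=
                 abs(coord - (hi * R + off + 1L)), lo, hi)
  pmin(pmax(pick, 0), n - 1L) + 1L
}

#' Block-quantize a label map to the feature grid geometry
#'
#' Gives every pixel the label its nearest grid cell center carries in
#' `map`. This is the ground truth "as seen" by a grid-based
#' segmentation: a pipeline that labels every feature point correctly
#' reproduces `quantize_labels(gt, R)` exactly, so recovery tests compare
#' against this rather than the pixel-exact ground truth.
#'
#' @param map integer label matrix.
#' @param R grid interval in pixels.
#' @return integer matrix of the same dimensions.
#' @export
quantize_labels <- function(map, R) {
  map <- unclass(map)
  h <- nrow(map); w <- ncol(map)
  R <- as.integer(R)
  if (R < 2L || R > min(h, w)) stop("R out of range", call. = FALSE)
  gr <- h %/% R; gc <- w %/% R
  off <- R %/% 2L
  centers_r <- (seq_len(gr) - 1L) * R + off + 1L
  centers_c <- (seq_len(gc) - 1L) * R + off + 1L
  cellv <- map[centers_r, centers_c, drop = FALSE]
  cellv[.nearest_cell(seq_len(h), R, gr),
        .nearest_cell(seq_len(w), R, gc), drop = FALSE]
}

#' Lift feature-point cluster labels to a full-resolution label map
#'
#' Every pixel receives the cluster label of its nearest feature point
#' (Euclidean distance; ties resolved toward the lower raster index,
#' i.e. lower grid row then lower grid column). Because the feature
#' points sit at regular cell centers this makes each R x R cell take its
#' own point's label, with the remainder strips at the right/bottom edges
#' inheriting from the nearest full cell.
#'
#' @param fp a `feature_points` object.
#' @param model a `cluster_model` over the same points.
#' @param height,width output dimensions; default the source image's.
#' @return integer H x W matrix of cluster labels in `1..M`
#'   (class `superpixel_map`).
#' @export
build_label_map <- function(fp, model, height = fp$height,
                            width = fp$width) {
  if (length(model$labels) != nrow(fp$points))
    stop("cluster model does not cover the feature points", call. = FALSE)
  if (height != fp$height || width != fp$width)
    stop("dimension mismatch with the feature grid", call. = FALSE)
  R <- fp$R
  gr <- fp$grid_rows; gc <- fp$grid_cols
  ridx <- .nearest_cell(seq_len(height), R, gr)
  cidx <- .nearest_cell(seq_len(width), R, gc)
  labm <- matrix(model$labels, nrow = gr, ncol = gc, byrow = TRUE)
  out <- labm[ridx, cidx, drop = FALSE]
  class(out) <- c("superpixel_map", class(out))
  out
}

#' Extract superpixel boundaries from a label map
#'
#' Flags every pixel having at least one 4-neighbor with a different
#' label; both sides of each interface are marked. For the one-sided
#' (thinned) variant used by the Boundary Recall denominator see
#' [boundary_pixels_thin()].
#'
#' @param map integer label matrix.
#' @return logical matrix of the same dimensions.
#' @export
extract_boundaries <- function(map) {
  map <- unclass(map)
  h <- nrow(map); w <- ncol(map)
  b <- matrix(FALSE, h, w)
  if (h > 1L) {
    dif <- map[-1, , drop = FALSE] != map[-h, , drop = FALSE]
    b[-h, ] <- b[-h, ] | dif
    b[-1, ] <- b[-1, ] | dif
  }
  if (w > 1L) {
    dif <- map[, -1, drop = FALSE] != map[, -w, drop = FALSE]
    b[, -w] <- b[, -w] | dif
    b[, -1] <- b[, -1] | dif
  }
  b
}

#' One-sided (thinned) boundary pixels of a label map
#'
#' Marks only the lexicographically first pixel of each differing
#' 4-neighbor pair (the pixel whose bottom or right neighbor differs),
#' so every interface is counted once.
#'
#' @param map integer label matrix.
#' @return logical matrix.
#' @export
boundary_pixels_thin <- function(map) {
  map <- unclass(map)
  h <- nrow(map); w <- ncol(map)
  b <- matrix(FALSE, h, w)
  if (h > 1L)
    b[-h, ] <- b[-h, ] | (map[-1, , drop = FALSE] != map[-h, , drop = FALSE])
  if (w > 1L)
    b[, -w] <- b[, -w] | (map[, -1, drop = FALSE] != map[, -w, drop = FALSE])
  b
}

#' Render a superpixel visualization of an RGB image
#'
#' `mean_fill` replaces every superpixel by its mean RGB color;
#' `boundary_overlay` draws boundary pixels in a fixed color over the
#' source image.
#'
#' @param rgb H x W x 3 RGB array.
#' @param map integer label matrix of matching dimensions.
#' @param mode `"mean_fill"` or `"boundary_overlay"`.
#' @param color length-3 RGB triple for the overlay (default black).
#' @return H x W x 3 RGB array.
#' @export
render_superpixel_image <- function(rgb, map,
                                    mode = c("mean_fill",
                                             "boundary_overlay"),
                                    color = c(0, 0, 0)) {
  mode <- match.arg(mode)
  map <- unclass(map)
  if (nrow(map) != dim(rgb)[1] || ncol(map) != dim(rgb)[2])
    stop("image and label map dimensions differ", call. = FALSE)
  out <- rgb
  if (mode == "mean_fill") {
    f <- factor(as.vector(map))
    for (ch in 1:3) {
      v <- as.vector(rgb[, , ch])
      means <- tapply(v, f, mean)
      out[, , ch] <- matrix(means[f], nrow(map), ncol(map))
    }
    out <- round(out)
  } else {
    b <- extract_boundaries(map)
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[b] <- color[ch]
      out[, , ch] <- plane
    }
  }
  out
}

#' Split spatially disconnected clusters into separate superpixels
#'
#' Optional post-processing: relabels each 4-connected component of the
#' label map with its own id (ids ordered by first raster occurrence,
#' column-major as stored). Off by default in the pipeline — spatial
#' connectivity is not part of the clustering itself.
#'
#' @param map integer label matrix.
#' @return integer matrix with labels `1..n_components`.
#' @export
enforce_connectivity <- function(map) {
  map <- unclass(map)
  h <- nrow(map); w <- ncol(map)
  out <- matrix(0L, h, w)
  comp <- 0L
  for (start in which(out == 0L)) {
    if (out[start] != 0L) next
    comp <- comp + 1L
    lab <- map[start]
    queue <- start; out[start] <- comp
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      for (d in c(-1L, 1L, -h, h)) {
        nb <- cur + d
        ok <- nb >= 1L & nb <= h * w & out[pmin(pmax(nb, 1L), h * w)] == 0L
        # forbid vertical wrap between column ends
        if (d == -1L) ok <- ok & ((cur - 1L) %% h != 0L)
        if (d ==  1L) ok <- ok & (cur %% h != 0L)
        nb <- nb[ok]
        nb <- nb[map[nb] == lab & out[nb] == 0L]
        if (length(nb)) {
          out[nb] <- comp
          queue <- c(queue, nb)
        }
      }
      queue <- unique(queue)
    }
  }
  class(out) <- c("superpixel_map", class(out))
  out
}
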