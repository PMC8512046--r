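#' Parameter bundle for grid-point density-peak segmentation
#'
#' Collects every tunable of the pipeline. Defaults follow the method's
#' worked parameterization: `K = 1.3 * R`, `psi = 13`, curve selection
#' with `a = 0.005`; `R = 8` is the efficiency/quality compromise default.
#'
#' @param R grid interval in pixels (integer >= 2). One feature point is
#'   placed per R x R cell.
#' @param K spatial neighborhood radius in pixels; default `1.3 * R`,
#'   which spans the four axial grid neighbors but not the diagonals.
#' @param psi color-similarity gate: squared Lab distance threshold.
#' @param a curve parameter of the inverse-function center selector
#'   (select points with rho' * delta' > a).
#' @param lambda_thresh threshold on lambda = rho' * delta' for the
#'   lambda selector (coincides with the curve rule at `a = lambda_thresh`).
#' @param M requested superpixel count for the top-M selector, or `NULL`.
#' @param strategy center-selection strategy: `"curve"`, `"lambda"`, or
#'   `"topM"` (requires `M`).
#' @param strict_literal logical; gate the spatial neighborhood on the
#'   *squared* distance vs `K` (the printed form) instead of the Euclidean
#'   distance. Off by default: the literal form makes `K = 1.3 R` capture
#'   no neighboring grid point.
#' @param squared_color logical; gate color on squared Lab distance vs
#'   `psi` (default, the printed form). `FALSE` gates on the unsquared
#'   distance.
#' @return object of class `grid_params`.
#' @export
grid_params <- function(R = 8L, K = 1.3 * R, psi = 13, a = 0.005,
                        lambda_thresh = 0.005, M = NULL,
                        strategy = c("curve", "lambda", "topM"),
                        strict_literal = FALSE, squared_color = TRUE) {
  strategy <- match.arg(strategy)
  R <- as.integer(R)
  if (is.na(R) || R < 2L) stop("R must be an integer >= 2", call. = FALSE)
  if (!is.numeric(K) || K <= 0) stop("K must be > 0", call. = FALSE)
  if (!is.numeric(psi) || psi <= 0) stop("psi must be > 0", call. = FALSE)
  if (!is.numeric(a) || a <= 0) stop("a must be > 0", call. = FALSE)
  if (!is.numeric(lambda_thresh) || lambda_thresh <= 0)
    stop("lambda_thresh must be > 0", call. = FALSE)
  if (!is.null(M)) {
    M <- as.integer(M)
    if (is.na(M) || M < 1L) stop("M must be an integer >= 1", call. = FALSE)
  }
  if (strategy == "topM" && is.null(M))
    stop("strategy 'topM' requires M", call. = FALSE)
  structure(list(R = R, K = K, psi = psi, a = a,
                 lambda_thresh = lambda_thresh, M = M, strategy = strategy,
                 strict_literal = strict_literal,
                 squared_color = squared_color),
            class = "grid_params")
}

#' @export
print.grid_params <- function(x, ...) {
  cat("grid_params: R =", x$R, " K =", format(x$K), " psi =", x$psi,
      " strategy =", x$strategy, "\n")
  cat("  a =", x$a, " lambda_thresh =", x$lambda_thresh,
      " M =", if (is.null(x$M)) "unset" else x$M, "\n")
  invisible(x)
}

# Per-cell index vectors: rows 1..floor(H/R) map to pixel rows; trailing
# remainder pixels (H mod R) belong to no cell at the feature stage.
.cell_breaks <- function(extent, R) {
  n <- extent %/% R
  list(n = n, start = (seq_len(n) - 1L) * R + 1L, end = seq_len(n) * R)
}

#' Extract grid feature points with mean-filtered Lab features
#'
#' Places one feature point at the center of every R x R grid cell:
#' row `R*(r-1) + floor(R/2) + 1`, `r = 1..floor(H/R)` (and likewise for
#' columns), which gives exactly `floor(H/R) * floor(W/R)` points. Each
#' point's features `(Lbar, abar, bbar)` are the arithmetic mean of the
#' Lab values over its R x R cell — a block mean filter over the image.
#' Remainder strips (when H or W is not divisible by R) get no feature
#' point of their own; they are attached to clusters at the label-map
#' stage.
#'
#' @param lab H x W x 3 Lab array from [rgb_to_lab()].
#' @param params a [grid_params()] object (only `R` is used).
#' @return object of class `feature_points`: list with `points` (data.frame
#'   with columns `m`, `h`, `w`, `Lbar`, `abar`, `bbar`; `m` is the
#'   row-major raster index, 1-based), `grid_rows`, `grid_cols`, `R`,
#'   `height`, `width`.
#' @export
extract_feature_points <- function(lab, params) {
  if (!inherits(params, "grid_params")) params <- do.call(grid_params, params)
  R <- params$R
  h <- dim(lab)[1]; w <- dim(lab)[2]
  if (R > min(h, w))
    stop("R (", R, ") exceeds an image dimension (", h, " x ", w, ")",
         call. = FALSE)
  rows <- .cell_breaks(h, R); cols <- .cell_breaks(w, R)
  gr <- rows$n; gc <- cols$n

  # Block means per channel: sum pixels into cells with rowsum on the
  # truncated image, row-group then column-group.
  block_mean <- function(ch) {
    sub <- ch[seq_len(gr * R), seq_len(gc * R), drop = FALSE]
    rg <- rowsum(sub, rep(seq_len(gr), each = R))        # gr x (gc*R)
    cg <- rowsum(t(rg), rep(seq_len(gc), each = R))      # gc x gr
    t(cg) / (R * R)                                      # gr x gc
  }
  Lm <- block_mean(lab[, , 1]); am <- block_mean(lab[, , 2])
  bm <- block_mean(lab[, , 3])

  off <- R %/% 2L
  hs <- (seq_len(gr) - 1L) * R + off + 1L
  ws <- (seq_len(gc) - 1L) * R + off + 1L
  # row-major raster order: row index varies slowest
  pts <- data.frame(
    m = seq_len(gr * gc),
    h = rep(hs, each = gc),
    w = rep(ws, times = gr),
    Lbar = as.vector(t(Lm)),
    abar = as.vector(t(am)),
    bbar = as.vector(t(bm))
  )
  structure(list(points = pts, grid_rows = gr, grid_cols = gc,
                 R = R, height = h, width = w),
            class = "feature_points")
}

#' @export
print.feature_points <- function(x, ...) {
  cat("feature_points:", nrow(x$points), "points (",
      x$grid_rows, "x", x$grid_cols, "), R =", x$R,
      ", image", x$height, "x", x$width, "\n")
  invisible(x)
}

#' Block-mean smoothed view of a Lab image
#'
#' Replaces every pixel by the mean of its R x R grid cell, reproducing
#' the mean-filtering effect of the feature extraction at full resolution.
#' Remainder strips at the right/bottom edges take the value of the
#' nearest full cell.
#'
#' @inheritParams extract_feature_points
#' @param R grid interval in pixels.
#' @return Lab array of the same dimensions.
#' @export
smoothed_image <- function(lab, R) {
  R <- as.integer(R)
  h <- dim(lab)[1]; w <- dim(lab)[2]
  if (R < 2L || R > min(h, w)) stop("R out of range", call. = FALSE)
  fp <- extract_feature_points(lab, grid_params(R = R))
  gr <- fp$grid_rows; gc <- fp$grid_cols
  ridx <- pmin((seq_len(h) - 1L) %/% R + 1L, gr)
  cidx <- pmin((seq_len(w) - 1L) %/% R + 1L, gc)
  out <- array(0, dim = dim(lab))
  for (ch in 1:3) {
    cellv <- matrix(fp$points[[ch + 3L]], nrow = gr, ncol = gc, byrow = TRUE)
    out[, , ch] <- cellv[ridx, cidx, drop = FALSE]
  }
  out
}

#' Export a feature-point table as CSV
#'
#' Columns `m, h, w, Lbar, abar, bbar` (1-based indices/coordinates).
#'
#' @param fp a `feature_points` object.
#' @param path output file path.
#' @export
write_feature_csv <- function(fp, path) {
  utils::write.csv(fp$points, path, row.names = FALSE)
  invisible(path)
}
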