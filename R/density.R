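#' Color-gated density of every feature point
#'
#' The density `rho` of a point p counts the feature points q (including
#' p itself) that lie within spatial radius `K` of p *and* whose mean Lab
#' features are within the color gate: squared Lab distance
#' `(Lq-Lp)^2 + (aq-ap)^2 + (bq-bp)^2 <= psi`. The spatial gate uses the
#' Euclidean pixel distance by default, so `K = 1.3 R` spans the four
#' axial grid neighbors; `strict_literal = TRUE` gates on the squared
#' distance instead.
#'
#' Neighbor search exploits the regular grid: only points within
#' `ceiling(K/R)` grid steps can pass the spatial gate, so the cost is
#' O(N * k) with k the neighborhood size, not O(N^2).
#'
#' @param fp a `feature_points` object.
#' @param K spatial radius in pixels (> 0).
#' @param psi color gate threshold (> 0).
#' @param strict_literal gate space on squared distance vs `K`.
#' @param squared_color gate color on squared Lab distance vs `psi`
#'   (default); `FALSE` uses the unsquared distance.
#' @return integer vector of densities, one per feature point, each >= 1.
#' @export
compute_density <- function(fp, K, psi, strict_literal = FALSE,
                            squared_color = TRUE) {
  if (!is.numeric(K) || K <= 0) stop("K must be > 0", call. = FALSE)
  if (!is.numeric(psi) || psi <= 0) stop("psi must be > 0", call. = FALSE)
  pts <- fp$points
  gr <- fp$grid_rows; gc <- fp$grid_cols
  R <- fp$R
  feats <- cbind(pts$Lbar, pts$abar, pts$bbar)
  # grid coordinates of point m (row-major): r = (m-1) %/% gc, c = (m-1) %% gc
  Kd <- if (strict_literal) sqrt(K) else K   # effective Euclidean radius
  s <- floor(Kd / R)                          # max grid steps either axis
  rho <- rep.int(1L, nrow(pts))               # self always counts
  if (nrow(pts) == 1L) return(rho)
  Lm <- matrix(feats[, 1], gr, gc, byrow = TRUE)
  am <- matrix(feats[, 2], gr, gc, byrow = TRUE)
  bm <- matrix(feats[, 3], gr, gc, byrow = TRUE)
  rhom <- matrix(0L, gr, gc)
  for (dr in -s:s) for (dc in -s:s) {
    if (dr == 0L && dc == 0L) next
    if ((dr * R)^2 + (dc * R)^2 > Kd^2) next
    r1 <- max(1L, 1L - dr):min(gr, gr - dr)
    c1 <- max(1L, 1L - dc):min(gc, gc - dc)
    r2 <- r1 + dr; c2 <- c1 + dc
    d2 <- (Lm[r1, c1, drop = FALSE] - Lm[r2, c2, drop = FALSE])^2 +
          (am[r1, c1, drop = FALSE] - am[r2, c2, drop = FALSE])^2 +
          (bm[r1, c1, drop = FALSE] - bm[r2, c2, drop = FALSE])^2
    pass <- if (squared_color) d2 <= psi else sqrt(d2) <= psi
    rhom[r1, c1] <- rhom[r1, c1] + pass
  }
  rho + as.integer(as.vector(t(rhom)))
}

#' Density ranking, separation delta and nearest-denser parent
#'
#' Sorts the points by density in descending order (ties broken by
#' ascending raster index `m`). For every rank after the first, `delta`
#' is the Euclidean pixel distance to the nearest point of strictly
#' smaller rank and `parent` is that point's raster index. The rank-0
#' (densest) point takes `delta = max` of all other deltas and has no
#' parent (`NA`). When several earlier-ranked points are exactly
#' equidistant, the earliest rank — the densest candidate, raster index
#' breaking density ties — becomes the parent: on the density plateaus
#' of homogeneous regions this attaches boundary points to the interior
#' of their own region rather than to an arbitrary neighbor.
#'
#' @param rho integer density vector.
#' @param positions two-column matrix of (row, col) pixel coordinates.
#' @param strict_literal logical; use squared distances for `delta`
#'   (matches the printed distance form).
#' @return list with `order` (raster indices in rank order), `rank`
#'   (0-based rank per point), `delta` and `parent` (per point, raster
#'   indexed; parent is `NA` for the densest point).
#' @export
compute_delta <- function(rho, positions, strict_literal = FALSE) {
  n <- length(rho)
  if (n < 2L)
    stop("delta is undefined for fewer than 2 points", call. = FALSE)
  positions <- as.matrix(positions)
  ord <- order(-rho, seq_len(n))        # descending rho, ties: low m first
  delta <- numeric(n); parent <- rep(NA_integer_, n)
  ph <- positions[ord, 1]; pw <- positions[ord, 2]
  for (k in 2:n) {
    d2 <- (ph[seq_len(k - 1L)] - ph[k])^2 + (pw[seq_len(k - 1L)] - pw[k])^2
    j <- which.min(d2)   # ties: earliest rank (denser, then lower m) wins
    delta[ord[k]] <- if (strict_literal) d2[j] else sqrt(d2[j])
    parent[ord[k]] <- ord[j]
  }
  delta[ord[1L]] <- max(delta[-ord[1L]])
  rank <- integer(n); rank[ord] <- seq_len(n) - 1L
  list(order = ord, rank = rank, delta = delta, parent = parent)
}

#' Min-max normalization to \[0, 1\]
#'
#' `(v - min) / (max - min)`; when all values are equal the output is all
#' zeros (documented degenerate convention).
#'
#' @param v numeric vector, non-empty.
#' @return numeric vector in \[0, 1\].
#' @export
normalize01 <- function(v) {
  if (length(v) == 0L) stop("cannot normalize an empty vector", call. = FALSE)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(0, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Build the full per-point density table
#'
#' Runs [compute_density()] and [compute_delta()], normalizes `rho` and
#' `delta` to \[0, 1\], and forms the center-ness score
#' `lam = rho_norm * delta_norm`.
#'
#' @param fp a `feature_points` object.
#' @param params a [grid_params()] object.
#' @return object of class `density_table`: data.frame with columns
#'   `m, h, w, rho, rank, delta, parent, rho_norm, delta_norm, lam`,
#'   plus attribute `order` (raster indices in descending-density order).
#' @export
density_table <- function(fp, params) {
  pts <- fp$points
  rho <- compute_density(fp, params$K, params$psi,
                         strict_literal = params$strict_literal,
                         squared_color = params$squared_color)
  dl <- compute_delta(rho, cbind(pts$h, pts$w),
                      strict_literal = params$strict_literal)
  tab <- data.frame(
    m = pts$m, h = pts$h, w = pts$w,
    rho = rho, rank = dl$rank, delta = dl$delta, parent = dl$parent,
    rho_norm = normalize01(rho), delta_norm = normalize01(dl$delta)
  )
  tab$lam <- tab$rho_norm * tab$delta_norm
  structure(tab, order = dl$order, class = c("density_table", "data.frame"))
}

#' Export a density table as CSV
#'
#' @param tab a `density_table`.
#' @param path output file path.
#' @export
write_density_csv <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}
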