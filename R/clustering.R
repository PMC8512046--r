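#' Select cluster centers above the inverse curve delta' = a / rho'
#'
#' A point is a center when its normalized density/separation product
#' exceeds `a`, i.e. it lies strictly above the hyperbola
#' `delta' = a / rho'` in the rho'-delta' plane. The densest (rank-0)
#' point is always forced into the center set. Centers are returned in
#' descending `lam` order (ties: ascending raster index).
#'
#' @param tab a [density_table()].
#' @param a curve parameter (> 0).
#' @return integer vector of center raster indices.
#' @export
select_centers_curve <- function(tab, a = 0.005) {
  if (!is.numeric(a) || a <= 0) stop("a must be > 0", call. = FALSE)
  sel <- tab$m[tab$lam > a]
  rank0 <- tab$m[tab$rank == 0L]
  sel <- union(sel, rank0)
  sel[order(-tab$lam[match(sel, tab$m)], sel)]
}

#' Select cluster centers by thresholding lambda
#'
#' Selects every point with `lam = rho' * delta'` strictly above
#' `lambda_thresh`, plus the rank-0 point unconditionally. Under the
#' inverse-curve reading this coincides exactly with
#' [select_centers_curve()] at `a = lambda_thresh`; both entry points are
#' kept because they are presented as separate rules.
#'
#' @param tab a [density_table()].
#' @param lambda_thresh threshold (> 0).
#' @return integer vector of center raster indices (descending `lam`).
#' @export
select_centers_lambda <- function(tab, lambda_thresh = 0.005) {
  if (!is.numeric(lambda_thresh) || lambda_thresh <= 0)
    stop("lambda_thresh must be > 0", call. = FALSE)
  select_centers_curve(tab, a = lambda_thresh)
}

#' Select exactly M cluster centers by top lambda
#'
#' Sorts `lam` in descending order (ties broken by ascending raster
#' index) and takes the first `M` points.
#'
#' @param tab a [density_table()].
#' @param M requested number of centers, `1 <= M <= N`.
#' @return integer vector of `M` center raster indices.
#' @export
select_centers_topM <- function(tab, M) {
  n <- nrow(tab)
  M <- as.integer(M)
  if (is.na(M) || M < 1L || M > n)
    stop("M must be in [1, ", n, "]", call. = FALSE)
  ord <- order(-tab$lam, tab$m)
  tab$m[ord[seq_len(M)]]
}

#' Assign every feature point to a center along denser-neighbor chains
#'
#' Each center labels itself. Every other point follows its `parent`
#' link (nearest strictly-denser point) transitively until a center is
#' reached and inherits that center's label. Chains always terminate:
#' parents have strictly smaller rank, and the rank-0 point is required
#' to be a center. Points are processed in rank order so each parent is
#' labeled before its children — a single O(N) pass.
#'
#' @param tab a [density_table()].
#' @param centers integer vector of center raster indices; must include
#'   the rank-0 point.
#' @return object of class `cluster_model`: list with `centers` (as
#'   given), `labels` (integer per feature point, in `1..M`; the i-th
#'   center's points carry label i) and `M`.
#' @export
assign_clusters <- function(tab, centers) {
  if (length(centers) == 0L) stop("centers must be non-empty", call. = FALSE)
  rank0 <- tab$m[tab$rank == 0L]
  if (!(rank0 %in% centers))
    stop("the densest (rank-0) point must be a center", call. = FALSE)
  n <- nrow(tab)
  labels <- integer(n)
  labels[centers] <- seq_along(centers)
  ord <- attr(tab, "order")
  if (is.null(ord)) ord <- order(tab$rank)
  for (m in ord) {
    if (labels[m] == 0L) labels[m] <- labels[tab$parent[m]]
  }
  structure(list(centers = as.integer(centers), labels = labels,
                 M = length(centers)),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("cluster_model:", x$M, "clusters over", length(x$labels),
      "feature points\n")
  invisible(x)
}

#' Select centers according to a parameter bundle
#'
#' Dispatches on `params$strategy` to the curve, lambda, or top-M rule.
#'
#' @param tab a [density_table()].
#' @param params a [grid_params()] object.
#' @return integer vector of center raster indices.
#' @export
select_centers <- function(tab, params) {
  switch(params$strategy,
         curve  = select_centers_curve(tab, params$a),
         lambda = select_centers_lambda(tab, params$lambda_thresh),
         topM   = select_centers_topM(tab, params$M))
}

#' Export cluster assignments as CSV
#'
#' Columns `m, label, is_center`.
#'
#' @param model a `cluster_model`.
#' @param path output file path.
#' @export
write_cluster_csv <- function(model, path) {
  df <- data.frame(m = seq_along(model$labels), label = model$labels,
                   is_center = seq_along(model$labels) %in% model$centers)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
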