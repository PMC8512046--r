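#' Run the full grid-point density-peak segmentation pipeline
#'
#' Lab conversion, grid feature extraction, color-gated density, center
#' selection, chain assignment, and label-map construction in one call.
#' The pipeline is deterministic: identical input and parameters always
#' give identical output.
#'
#' @param rgb H x W x 3 RGB array in \[0, 255\].
#' @param params a [grid_params()] object.
#' @param srgb apply sRGB linearization before the Lab matrix.
#' @param connectivity split spatially disconnected superpixels into
#'   separate labels afterwards (off by default).
#' @return object of class `gp_segmentation`: list with `lab`, `features`
#'   (`feature_points`), `table` (`density_table`), `centers`, `model`
#'   (`cluster_model`), `map` (`superpixel_map`), `M` (superpixel count in
#'   the map, post-split when `connectivity = TRUE`) and `params`.
#' @examples
#' scene <- make_two_region(48, 64, noise_sd = 0)
#' seg <- segment_image(scene$rgb, grid_params(R = 8, strategy = "topM",
#'                                             M = 2))
#' seg$M
#' @export
segment_image <- function(rgb, params = grid_params(), srgb = FALSE,
                          connectivity = FALSE) {
  validate_rgb(rgb)
  lab <- rgb_to_lab(rgb, srgb = srgb)
  fp <- extract_feature_points(lab, params)
  if (nrow(fp$points) < 2L) {
    # degenerate single-point grid: one cluster, no delta defined
    model <- structure(list(centers = 1L, labels = 1L, M = 1L),
                       class = "cluster_model")
    tab <- NULL
  } else {
    tab <- density_table(fp, params)
    centers <- select_centers(tab, params)
    model <- assign_clusters(tab, centers)
  }
  map <- build_label_map(fp, model)
  if (connectivity) map <- enforce_connectivity(map)
  structure(list(lab = lab, features = fp, table = tab,
                 centers = model$centers, model = model, map = map,
                 M = length(unique(as.vector(unclass(map)))),
                 params = params),
            class = "gp_segmentation")
}

#' @export
print.gp_segmentation <- function(x, ...) {
  cat("gp_segmentation:", x$M, "superpixels,",
      nrow(x$features$points), "feature points, R =", x$params$R, "\n")
  invisible(x)
}
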