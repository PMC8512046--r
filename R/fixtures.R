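# Synthetic piecewise-constant scenes with known ground truth. Region
# colors are stated in Lab (the pipeline's working space), converted to
# RGB through the package's own inverse transform, then i.i.d. Gaussian
# channel noise is added in RGB space and clipped to [0, 255].

.scene_from_regions <- function(gt, palette_lab, noise_sd, seed) {
  h <- nrow(gt); w <- ncol(gt)
  lab <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3)
    lab[, , ch] <- matrix(vapply(palette_lab, `[`, numeric(1), ch)[gt],
                          h, w)
  rgb <- lab_to_rgb(lab)
  if (noise_sd > 0) {
    set.seed(seed)
    rgb <- rgb + stats::rnorm(length(rgb), sd = noise_sd)
    rgb <- round(pmin(pmax(rgb, 0), 255))
  }
  structure(list(rgb = rgb, gt = gt, region_colors = palette_lab,
                 seed = seed),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("synthetic_scene:", nrow(x$gt), "x", ncol(x$gt), ",",
      length(unique(as.vector(x$gt))), "region(s), seed", x$seed, "\n")
  invisible(x)
}

#' Two-region vertical-split synthetic scene
#'
#' Left and right half-planes with the given Lab colors, plus i.i.d.
#' Gaussian channel noise (RGB space, clipped to \[0, 255\]).
#' Deterministic for a fixed seed.
#'
#' @param height,width image dimensions (>= 1).
#' @param color_left,color_right Lab triples of the two regions.
#' @param noise_sd channel noise standard deviation (8-bit units).
#' @param seed integer RNG seed.
#' @return `synthetic_scene`: list with `rgb` (H x W x 3 array), `gt`
#'   (integer label matrix), `region_colors`, `seed`.
#' @export
make_two_region <- function(height, width,
                            color_left = c(40, 25, 20),
                            color_right = c(70, -30, -25),
                            noise_sd = 2, seed = 1L) {
  if (height < 1L || width < 1L) stop("invalid dimensions", call. = FALSE)
  gt <- matrix(1L, height, width)
  gt[, seq_len(width) > width / 2] <- 2L
  .scene_from_regions(gt, list(color_left, color_right), noise_sd, seed)
}

#' Centered-disk synthetic scene
#'
#' Disk of radius `radius` centered in the image over a constant
#' background; `radius = 0` (or a radius covering the whole frame)
#' degenerates to a single region.
#'
#' @inheritParams make_two_region
#' @param bg,fg Lab triples of background and disk.
#' @param radius disk radius in pixels.
#' @return `synthetic_scene`.
#' @export
make_disk <- function(height, width,
                      bg = c(75, 5, 40), fg = c(35, -35, -5),
                      radius = min(height, width) / 4,
                      noise_sd = 2, seed = 1L) {
  if (height < 1L || width < 1L) stop("invalid dimensions", call. = FALSE)
  cy <- (height + 1) / 2; cx <- (width + 1) / 2
  d2 <- outer((seq_len(height) - cy)^2, (seq_len(width) - cx)^2, `+`)
  inside <- d2 <= radius^2
  gt <- matrix(1L, height, width)
  gt[inside] <- 2L
  if (all(inside) || !any(inside)) gt[] <- 1L
  pal <- if (any(gt == 2L)) list(bg, fg) else list(if (all(inside)) fg else bg)
  .scene_from_regions(gt, pal, noise_sd, seed)
}

#' Voronoi-mosaic synthetic scene
#'
#' Partition of the frame into the Voronoi cells of `n_sites` uniformly
#' random sites; cell colors are drawn from `palette` by greedy graph
#' coloring so that adjacent cells always differ (an error is raised when
#' the palette is too small for the adjacency).
#'
#' @inheritParams make_two_region
#' @param n_sites number of Voronoi sites (>= 1).
#' @param palette list of Lab triples; adjacent cells get different
#'   entries. The default five colors are mutually far beyond the
#'   pipeline's color gate.
#' @return `synthetic_scene`; `gt` labels are the Voronoi cells.
#' @export
make_voronoi_mosaic <- function(height, width, n_sites = 5,
                                palette = list(c(30, 20, 30),
                                               c(80, -10, 40),
                                               c(55, 45, -20),
                                               c(45, -40, 25),
                                               c(70, 20, -45)),
                                noise_sd = 2, seed = 1L) {
  if (n_sites < 1L) stop("n_sites must be >= 1", call. = FALSE)
  set.seed(seed)
  sy <- stats::runif(n_sites, 1, height)
  sx <- stats::runif(n_sites, 1, width)
  gt <- matrix(0L, height, width)
  best <- matrix(Inf, height, width)
  for (s in seq_len(n_sites)) {
    d2 <- outer((seq_len(height) - sy[s])^2, (seq_len(width) - sx[s])^2, `+`)
    upd <- d2 < best
    gt[upd] <- s
    best[upd] <- d2[upd]
  }
  # cells can be empty when sites nearly coincide; compact the labels
  used <- sort(unique(as.vector(gt)))
  gt <- matrix(match(gt, used), height, width)
  k <- length(used)
  adj <- .label_adjacency(gt, k)
  coloring <- .greedy_color(adj, length(palette))
  if (is.null(coloring))
    stop("palette too small to color adjacent Voronoi cells distinctly",
         call. = FALSE)
  pal <- palette[coloring]
  # seed + 1: the site stream above must not be reused for the noise
  .scene_from_regions(gt, pal, noise_sd, seed + 1L)
}

.label_adjacency <- function(gt, k) {
  adj <- matrix(FALSE, k, k)
  h <- nrow(gt); w <- ncol(gt)
  if (h > 1L) {
    a <- gt[-h, ]; b <- gt[-1, ]
    idx <- a != b
    adj[cbind(a[idx], b[idx])] <- TRUE
  }
  if (w > 1L) {
    a <- gt[, -w]; b <- gt[, -1]
    idx <- a != b
    adj[cbind(a[idx], b[idx])] <- TRUE
  }
  adj | t(adj)
}

.greedy_color <- function(adj, n_colors) {
  k <- nrow(adj)
  col <- integer(k)
  for (v in order(-rowSums(adj))) {
    taken <- unique(col[adj[v, ] & col > 0L])
    free <- setdiff(seq_len(n_colors), taken)
    if (!length(free)) return(NULL)
    col[v] <- free[1L]
  }
  col
}

#' Write a scene's standard fixture files
#'
#' Writes `<stem>.ppm` (ASCII PPM image; `<stem>.png` instead when the
#' `png` package is available) and `<stem>_gt.csv` (ground-truth label
#' matrix).
#'
#' @param scene a `synthetic_scene`.
#' @param stem output path stem (no extension).
#' @return character vector of the files written.
#' @export
write_scene <- function(scene, stem) {
  img <- if (requireNamespace("png", quietly = TRUE)) {
    p <- paste0(stem, ".png"); write_image(scene$rgb, p); p
  } else {
    p <- paste0(stem, ".ppm"); write_image(scene$rgb, p); p
  }
  gtp <- paste0(stem, "_gt.csv")
  write_label_csv(scene$gt, gtp)
  invisible(c(img, gtp))
}
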