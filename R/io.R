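# Image I/O. PNG/JPEG are handled through the `png`/`jpeg` packages when
# available; ASCII netpbm (P2/P3) is implemented here so the package
# works with plain-text images in any environment. Images are numeric
# H x W x 3 arrays in [0, 255] throughout.

.tokens <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- sub("#.*$", "", txt)          # strip netpbm comments
  scan(text = paste(txt, collapse = " "), what = character(),
       quiet = TRUE)
}

.read_pnm <- function(path) {
  tok <- .tokens(path)
  magic <- tok[1]
  if (!magic %in% c("P2", "P3"))
    stop("unsupported netpbm type '", magic, "' (only ASCII P2/P3)",
         call. = FALSE)
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  maxval <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)]) * (255 / maxval)
  if (magic == "P2") {
    matrix(vals, nrow = h, ncol = w, byrow = TRUE)  # gray; promoted upstream
  } else {
    px <- matrix(vals, ncol = 3L, byrow = TRUE)  # per-pixel RGB, row-major
    arr <- array(0, dim = c(h, w, 3L))
    for (ch in 1:3)
      arr[, , ch] <- matrix(px[, ch], nrow = h, ncol = w, byrow = TRUE)
    arr
  }
}

.write_ppm <- function(rgb, path) {
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  px <- round(cbind(as.vector(t(rgb[, , 1])),
                    as.vector(t(rgb[, , 2])),
                    as.vector(t(rgb[, , 3]))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  writeLines(paste(px[, 1], px[, 2], px[, 3]), con)
  invisible(path)
}

#' Read an image as an 8-bit RGB array
#'
#' Supports PNG and JPEG (via the `png`/`jpeg` packages when installed)
#' and ASCII netpbm (`.ppm`/`.pgm`, types P3/P2). Grayscale inputs are
#' promoted to 3 channels by replication; an alpha channel is dropped.
#'
#' @param path image file path.
#' @return numeric H x W x 3 array with values in \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stop("reading PNG requires the 'png' package", call. = FALSE)
      png::readPNG(path) * 255
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      jpeg::readJPEG(path) * 255
    },
    ppm = ,
    pgm = .read_pnm(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(arr)) == 2L) {
    message("grayscale input promoted to 3 channels: ", path)
    arr <- array(rep(arr, 3), dim = c(dim(arr), 3L))
  } else if (dim(arr)[3] == 4L) {
    arr <- arr[, , 1:3, drop = FALSE]
  } else if (dim(arr)[3] == 1L) {
    message("grayscale input promoted to 3 channels: ", path)
    arr <- array(rep(arr, 3), dim = c(dim(arr)[1:2], 3L))
  }
  arr
}

#' Write an 8-bit RGB array to an image file
#'
#' Format chosen by extension: `.png` (requires the `png` package) or
#' `.ppm` (ASCII, always available).
#'
#' @param rgb H x W x 3 array in \[0, 255\].
#' @param path output path.
#' @export
write_image <- function(rgb, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("writing PNG requires the 'png' package", call. = FALSE)
    png::writePNG(round(rgb) / 255, path)
  } else if (ext == "ppm") {
    .write_ppm(rgb, path)
  } else stop("unsupported output format: .", ext, call. = FALSE)
  invisible(path)
}

#' Read an integer label map
#'
#' `.csv` files are read as a headerless integer matrix; `.png` files as
#' a single-channel image whose (16-bit) intensities are the labels.
#'
#' @param path file path.
#' @return integer matrix.
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    m <- as.matrix(utils::read.csv(path, header = FALSE))
    dimnames(m) <- NULL
    storage.mode(m) <- "integer"
    m
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("reading PNG requires the 'png' package", call. = FALSE)
    arr <- png::readPNG(path, info = TRUE)
    depth <- attr(arr, "info")$bit.depth
    scale <- 2^depth - 1
    if (length(dim(arr)) == 3L && dim(arr)[3] >= 2L) {
      # two-byte encoding written by write_label_csv: label = 256*R + G
      m <- round(arr[, , 1] * scale) * 256L + round(arr[, , 2] * scale)
    } else {
      if (length(dim(arr)) == 3L) arr <- arr[, , 1]
      m <- round(arr * scale)
    }
    m <- matrix(m, dim(arr)[1], dim(arr)[2])
    storage.mode(m) <- "integer"
    m
  } else stop("unsupported label-map format: .", ext, call. = FALSE)
}

#' Write an integer label map
#'
#' `.csv` writes a headerless integer matrix (the canonical lossless
#' format). `.png` writes an RGB image carrying each 16-bit label in two
#' bytes (`R` = high byte, `G` = low byte, `B` = 0) — the installed PNG
#' writer has no 16-bit grayscale mode, so this keeps the round-trip
#' exact for labels in \[0, 65535\]; [read_label_map()] decodes it.
#'
#' @param map integer matrix.
#' @param path output path.
#' @export
write_label_csv <- function(map, path) {
  ext <- tolower(tools::file_ext(path))
  map <- unclass(map)
  if (ext == "csv") {
    utils::write.table(map, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("writing PNG requires the 'png' package", call. = FALSE)
    if (max(map) > 65535L) stop("labels exceed 16-bit range", call. = FALSE)
    arr <- array(0, dim = c(nrow(map), ncol(map), 3L))
    arr[, , 1] <- (map %/% 256L) / 255
    arr[, , 2] <- (map %% 256L) / 255
    png::writePNG(arr, path)
  } else stop("unsupported label-map format: .", ext, call. = FALSE)
  invisible(path)
}

#' Bilinear resize of an RGB array
#'
#' Standard bilinear resampling with pixel-center alignment. Offered as
#' explicit preprocessing (e.g. to the 320 x 240 working size); the
#' segmentation pipeline itself never resizes implicitly.
#'
#' @param rgb H x W x 3 array.
#' @param height,width target dimensions.
#' @return resized array.
#' @export
resize_bilinear <- function(rgb, height, width) {
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  ys <- (seq_len(height) - 0.5) * h / height + 0.5
  xs <- (seq_len(width) - 0.5) * w / width + 0.5
  y0 <- pmin(pmax(floor(ys), 1L), h); y1 <- pmin(y0 + 1L, h)
  x0 <- pmin(pmax(floor(xs), 1L), w); x1 <- pmin(x0 + 1L, w)
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, dim = c(height, width, 3L))
  for (ch in 1:3) {
    p <- rgb[, , ch]
    top <- p[y0, x0, drop = FALSE] * rep(1 - fx, each = height) +
           p[y0, x1, drop = FALSE] * rep(fx, each = height)
    bot <- p[y1, x0, drop = FALSE] * rep(1 - fx, each = height) +
           p[y1, x1, drop = FALSE] * rep(fx, each = height)
    out[, , ch] <- top * (1 - fy) + bot * fy
  }
  out
}
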