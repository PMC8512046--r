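# XYZ <- M %*% RGB with channels scaled to [0, 1]; each row sums to the
# matching white-point component so pure white maps to L = 100, a = b = 0.
.rgb2xyz <- matrix(c(
  0.4124, 0.3576, 0.1805,
  0.2126, 0.7152, 0.0722,
  0.0193, 0.1192, 0.9505
), nrow = 3, byrow = TRUE)

.white_point <- c(X = 0.9505, Y = 1.0, Z = 1.089)

# CIE piecewise companding: cube root above (6/29)^3, linearized below.
.lab_f <- function(t) {
  thr <- (6 / 29)^3
  ifelse(t > thr, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
}

.lab_f_inv <- function(ft) {
  thr <- 6 / 29
  ifelse(ft > thr, ft^3, 3 * thr^2 * (ft - 4 / 29))
}

# sRGB electro-optical transfer (and inverse), used only when srgb = TRUE.
.srgb_linearize <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}

.srgb_delinearize <- function(u) {
  ifelse(u <= 0.0031308, 12.92 * u, 1.055 * u^(1 / 2.4) - 0.055)
}

#' Validate an 8-bit RGB image array
#'
#' @param x object to check: numeric H x W x 3 array with integer-valued
#'   entries in \[0, 255\].
#' @return `x`, invisibly, after validation.
#' @keywords internal
validate_rgb <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("RGB image must be an H x W x 3 array", call. = FALSE)
  if (dim(x)[3] != 3L)
    stop("RGB image must have exactly 3 channels, got ", dim(x)[3],
         call. = FALSE)
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    stop("RGB image must have height >= 1 and width >= 1", call. = FALSE)
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    stop("RGB channel values must lie in [0, 255]", call. = FALSE)
  invisible(x)
}

#' Convert an 8-bit RGB image to CIELAB
#'
#' Applies the fixed 3x3 RGB-to-XYZ matrix to channel values scaled to
#' \[0, 1\], then the CIELAB transform with white point
#' (Xn, Yn, Zn) = (0.9505, 1.0, 1.089). By default no gamma expansion is
#' performed: the matrix is applied to linearly scaled channel values.
#' Set `srgb = TRUE` to linearize with the standard sRGB curve first
#' (color-accurate mode).
#'
#' @param rgb numeric H x W x 3 array, values in \[0, 255\].
#' @param srgb logical; apply sRGB linearization before the matrix.
#' @return H x W x 3 array with channels L (\[0, 100\]), a, b.
#' @examples
#' img <- array(128, dim = c(4, 4, 3))
#' lab <- rgb_to_lab(img)
#' lab[1, 1, ]  # gray: a = b = 0
#' @export
rgb_to_lab <- function(rgb, srgb = FALSE) {
  validate_rgb(rgb)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  chan <- matrix(rgb, ncol = 3L) / 255
  if (srgb) chan <- .srgb_linearize(chan)
  xyz <- chan %*% t(.rgb2xyz)
  fx <- .lab_f(xyz[, 1] / .white_point[["X"]])
  fy <- .lab_f(xyz[, 2] / .white_point[["Y"]])
  fz <- .lab_f(xyz[, 3] / .white_point[["Z"]])
  lab <- cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
  array(lab, dim = c(h, w, 3L))
}

#' Convert a CIELAB image back to 8-bit RGB
#'
#' Exact inverse of [rgb_to_lab()] up to the \[0, 255\] clip and integer
#' rounding. Used mainly by the synthetic fixture generators, which state
#' region colors in Lab.
#'
#' @param lab numeric H x W x 3 array with channels L, a, b.
#' @param srgb logical; apply the sRGB transfer curve after the inverse
#'   matrix (matches `rgb_to_lab(srgb = TRUE)`).
#' @param round logical; round to whole 8-bit intensities (default).
#' @return H x W x 3 array with values in \[0, 255\].
#' @export
lab_to_rgb <- function(lab, srgb = FALSE, round = TRUE) {
  if (!is.array(lab) || length(dim(lab)) != 3L || dim(lab)[3] != 3L)
    stop("Lab image must be an H x W x 3 array", call. = FALSE)
  h <- dim(lab)[1]; w <- dim(lab)[2]
  m <- matrix(lab, ncol = 3L)
  fy <- (m[, 1] + 16) / 116
  fx <- fy + m[, 2] / 500
  fz <- fy - m[, 3] / 200
  xyz <- cbind(.lab_f_inv(fx) * .white_point[["X"]],
               .lab_f_inv(fy) * .white_point[["Y"]],
               .lab_f_inv(fz) * .white_point[["Z"]])
  chan <- xyz %*% t(solve(.rgb2xyz))
  if (srgb) chan <- .srgb_delinearize(pmax(chan, 0))
  chan <- pmin(pmax(chan, 0), 1) * 255
  if (round) chan <- round(chan)
  array(chan, dim = c(h, w, 3L))
}
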