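#' phenoscan: image-based seedling phenotyping and QTL interval mapping
#'
#' Tools for segmenting green seedlings in RGB images via HSI/CIELAB
#' channel thresholding, extracting projected plant height and pixel
#' area, summarising traits across a recombinant inbred line (RIL)
#' population, and scanning for QTL by Haley-Knott regression interval
#' mapping with genome-wide permutation thresholds.
#'
#' @keywords internal
"_PACKAGE"

# ---- RGB image container ----------------------------------------------------

#' Construct and validate an RGB image
#'
#' An RGB image is an H x W x 3 numeric array of integer channel values
#' in 0-255, row 1 at the image top. This is the raw input of the
#' imaging pipeline.
#'
#' @param pixels H x W x 3 array of values in 0-255.
#' @return The validated array with class `rgb_image`.
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (anyNA(pixels) || !all(is.finite(pixels)))
    stop("image contains non-finite values", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]", call. = FALSE)
  structure(pixels, class = "rgb_image")
}

as_rgb_image <- function(img) {
  if (inherits(img, "rgb_image")) return(img)
  rgb_image(img)
}

# ---- HSI --------------------------------------------------------------------

#' Convert an RGB image to HSI (hue, saturation, intensity)
#'
#' Uses the geometric (arccos) HSI definition: intensity is the channel
#' mean, saturation is `1 - min/mean`, and hue is the angle of the pixel
#' color around the gray axis, in degrees with pure red at 0 and
#' `B > G` colors mapped to (180, 360).
#'
#' Hue is undefined for achromatic pixels (R = G = B). These carry hue 0
#' together with `achromatic = TRUE` (saturation below 1e-6), so that
#' downstream thresholding stays well defined on dense arrays.
#'
#' @param img An [rgb_image()] (or coercible array).
#' @return A list of class `hsi_image` with H x W matrices `hue_deg`
#'   (degrees in \[0, 360)), `saturation` and `intensity` (both in
#'   \[0, 1\]), and logical `achromatic`.
#' @export
rgb_to_hsi <- function(img) {
  img <- as_rgb_image(img)
  d <- dim(img)
  r <- matrix(img[, , 1], d[1], d[2]) / 255
  g <- matrix(img[, , 2], d[1], d[2]) / 255
  b <- matrix(img[, , 3], d[1], d[2]) / 255
  total <- r + g + b
  intensity <- total / 3
  mn <- pmin(r, g, b)
  saturation <- ifelse(total > 0, 1 - 3 * mn / total, 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  achromatic <- saturation < 1e-6
  cosang <- ifelse(den > 0, pmin(pmax(num / den, -1), 1), 1)
  theta <- acos(cosang) * 180 / pi
  hue <- ifelse(b > g, 360 - theta, theta)
  hue[achromatic] <- 0
  hue[hue >= 360] <- 0   # 360 - acos(1) rounds onto the origin
  structure(
    list(hue_deg = hue, saturation = saturation, intensity = intensity,
         achromatic = achromatic),
    class = "hsi_image")
}

# ---- CIELAB -----------------------------------------------------------------

# sRGB (IEC 61966-2-1) linear-light matrix, derived from the sRGB
# primary chromaticities and the D65 2-degree white point (x, y) =
# (0.3127, 0.3290) so matrix and Lab white normalisation share one set
# of defining constants.
.xyY_to_XYZ <- function(xy) c(xy[1] / xy[2], 1, (1 - xy[1] - xy[2]) / xy[2])
.d65_white <- .xyY_to_XYZ(c(0.3127, 0.3290))
.srgb_to_xyz <- local({
  prim <- cbind(.xyY_to_XYZ(c(0.64, 0.33)),   # R
                .xyY_to_XYZ(c(0.30, 0.60)),   # G
                .xyY_to_XYZ(c(0.15, 0.06)))   # B
  prim %*% diag(as.vector(solve(prim, .d65_white)))
})

.srgb_linearize <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}

.lab_f <- function(t) {
  delta <- 6 / 29
  ifelse(t > delta^3, t^(1 / 3), t / (3 * delta^2) + 4 / 29)
}

#' Convert an RGB image to CIELAB
#'
#' Pixels are interpreted as 8-bit sRGB and converted through linear
#' light and CIE XYZ to CIELAB under the D65 reference white
#' (2-degree observer).
#'
#' @param img An [rgb_image()] (or coercible array).
#' @return A list of class `lab_image` with H x W matrices `L` (0-100),
#'   `a_star` (green negative, red positive) and `b_star` (blue
#'   negative, yellow positive).
#' @export
rgb_to_lab <- function(img) {
  img <- as_rgb_image(img)
  d <- dim(img)
  rgb_lin <- .srgb_linearize(matrix(as.numeric(img), ncol = 3) / 255)
  xyz <- rgb_lin %*% t(.srgb_to_xyz)
  fx <- .lab_f(xyz[, 1] / .d65_white[1])
  fy <- .lab_f(xyz[, 2] / .d65_white[2])
  fz <- .lab_f(xyz[, 3] / .d65_white[3])
  structure(
    list(L = matrix(116 * fy - 16, d[1], d[2]),
         a_star = matrix(500 * (fx - fy), d[1], d[2]),
         b_star = matrix(200 * (fy - fz), d[1], d[2])),
    class = "lab_image")
}

# ---- 0-255 channel rescaling ------------------------------------------------

#' Rescale CIELAB and hue channels to a common 0-255 range
#'
#' The three channels used for seedling color classification are put on
#' a common 8-bit-like scale:
#' \deqn{Y_{a^*} = \{(a^* + 100)/200\} \times 255}
#' \deqn{Y_{b^*} = \{(b^* + 100)/200\} \times 255}
#' \deqn{Y_H = (H/360) \times 255}
#' a* and b* values outside \[-100, 100\] are clipped first so the
#' output honours the 0-255 contract.
#'
#' @param a_star,b_star Finite a*/b* channel values (any shape).
#' @param hue_deg Hue in degrees, in \[0, 360\].
#' @return Values in \[0, 255\], same shape as the input.
#' @export
scale_a_channel <- function(a_star) {
  if (anyNA(a_star) || !all(is.finite(a_star)))
    stop("a* values must be finite", call. = FALSE)
  (pmin(pmax(a_star, -100), 100) + 100) / 200 * 255
}

#' @rdname scale_a_channel
#' @export
scale_b_channel <- function(b_star) {
  if (anyNA(b_star) || !all(is.finite(b_star)))
    stop("b* values must be finite", call. = FALSE)
  (pmin(pmax(b_star, -100), 100) + 100) / 200 * 255
}

#' @rdname scale_a_channel
#' @export
scale_hue_channel <- function(hue_deg) {
  if (anyNA(hue_deg) || !all(is.finite(hue_deg)))
    stop("hue values must be finite", call. = FALSE)
  if (any(hue_deg < 0 | hue_deg > 360))
    stop("hue must lie in [0, 360] degrees", call. = FALSE)
  hue_deg / 360 * 255
}

#' Build the scaled hue/a*/b* channel stack of an image
#'
#' Runs [rgb_to_hsi()] and [rgb_to_lab()] and rescales the hue, a* and
#' b* planes to 0-255 with the channel rescaling equations. This stack
#' is the input to [channel_threshold_mask()].
#'
#' @param img An [rgb_image()] (or coercible array).
#' @return A list of class `channel_stack` with H x W matrices `y_hue`,
#'   `y_a`, `y_b` (all in \[0, 255\]) and the logical `achromatic` plane
#'   from the HSI conversion.
#' @export
build_channel_stack <- function(img) {
  img <- as_rgb_image(img)
  hsi <- rgb_to_hsi(img)
  lab <- rgb_to_lab(img)
  structure(
    list(y_hue = scale_hue_channel(hsi$hue_deg),
         y_a = scale_a_channel(lab$a_star),
         y_b = scale_b_channel(lab$b_star),
         achromatic = hsi$achromatic),
    class = "channel_stack")
}
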