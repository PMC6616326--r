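# Binary mask segmentation: channel thresholding + mask refinement.
#
# All mask operators work on plain logical matrices (row 1 = image top).
# Boundary conventions are part of the contract:
#   * majority (median) filter: replicate padding,
#   * erosion/dilation: outside the frame counts as background,
#   * hole filling: background 4-connectivity,
#   * small-component removal: foreground 8-connectivity.

#' Segmentation configuration
#'
#' Free parameters of the plant-mask pipeline. The channel thresholds
#' are calibration knobs on the 0-255 rescaled axes, not measured
#' constants: the defaults bracket green-to-yellow vegetation
#' (hue window (35, 120) is roughly 49-169 degrees) and are meant to be
#' tuned per imaging rig.
#'
#' @param hue_window Length-2 numeric, (low, high) on the scaled hue
#'   axis; pixels inside the window pass the hue gate.
#' @param a_green_max Pixels with scaled a* at or below this value count
#'   as green (a* is negative for green tissue).
#' @param b_yellow_min Pixels with scaled b* at or above this value
#'   count as yellow (b* is positive for yellow tissue).
#' @param median_radius Radius (px) of the majority/median denoise
#'   filter; 0 disables it.
#' @param morph_size Side (px, odd) of the square structuring element
#'   used for morphological opening.
#' @param morph_iterations Number of opening passes; 0 disables.
#' @param min_component_area Foreground components (8-connected) smaller
#'   than this many pixels are dropped from the final mask.
#' @return A list of class `seg_config`.
#' @export
seg_config <- function(hue_window = c(35, 120), a_green_max = 120,
                       b_yellow_min = 135, median_radius = 1,
                       morph_size = 3, morph_iterations = 1,
                       min_component_area = 20) {
  if (length(hue_window) != 2L || !all(is.finite(hue_window)))
    stop("`hue_window` must be two finite numbers", call. = FALSE)
  if (hue_window[1] >= hue_window[2])
    stop("degenerate hue window: low must be < high", call. = FALSE)
  if (median_radius < 0) stop("`median_radius` must be >= 0", call. = FALSE)
  if (morph_size < 1 || morph_size %% 2 != 1)
    stop("`morph_size` must be a positive odd integer", call. = FALSE)
  if (morph_iterations < 0) stop("`morph_iterations` must be >= 0", call. = FALSE)
  if (min_component_area < 0) stop("`min_component_area` must be >= 0", call. = FALSE)
  structure(
    list(hue_window = as.numeric(hue_window),
         a_green_max = as.numeric(a_green_max),
         b_yellow_min = as.numeric(b_yellow_min),
         median_radius = as.integer(median_radius),
         morph_size = as.integer(morph_size),
         morph_iterations = as.integer(morph_iterations),
         min_component_area = as.integer(min_component_area)),
    class = "seg_config")
}

as_mask <- function(mask) {
  if (is.logical(mask) && is.matrix(mask)) return(mask)
  if (is.matrix(mask)) return(mask != 0)
  stop("mask must be a logical matrix", call. = FALSE)
}

#' Threshold the scaled channel stack into a raw plant mask
#'
#' A pixel is kept when its scaled hue lies inside the yellow-to-green
#' hue window AND it is either strongly green (scaled a* at or below
#' `a_green_max`) or senescent yellow (scaled b* at or above
#' `b_yellow_min`). Achromatic pixels (undefined hue) never pass.
#'
#' @param stack A [build_channel_stack()] result.
#' @param cfg A [seg_config()].
#' @return Logical H x W matrix.
#' @export
channel_threshold_mask <- function(stack, cfg = seg_config()) {
  stopifnot(inherits(stack, "channel_stack"), inherits(cfg, "seg_config"))
  hue_ok <- stack$y_hue >= cfg$hue_window[1] & stack$y_hue <= cfg$hue_window[2] &
    !stack$achromatic
  color_ok <- stack$y_a <= cfg$a_green_max | stack$y_b >= cfg$b_yellow_min
  hue_ok & color_ok
}

pad_replicate <- function(m, r) {
  ri <- c(rep(1L, r), seq_len(nrow(m)), rep(nrow(m), r))
  ci <- c(rep(1L, r), seq_len(ncol(m)), rep(ncol(m), r))
  m[ri, ci, drop = FALSE]
}

# Sum of all (2r+1)^2 shifted copies of a padded numeric matrix.
neighborhood_sum <- function(m, r, pad) {
  nr <- nrow(m); nc <- ncol(m)
  acc <- matrix(0, nr, nc)
  for (dr in -r:r) for (dc in -r:r) {
    acc <- acc + pad[(1 + r + dr):(nr + r + dr), (1 + r + dc):(nc + r + dc)]
  }
  acc
}

#' Majority (median) filter for a binary mask
#'
#' Each pixel is replaced by the median of its (2r+1) x (2r+1)
#' neighborhood; for a binary mask this is the neighborhood majority
#' (the window has an odd pixel count, so there are no ties). The image
#' border is handled by replicate padding. Radius 0 is the identity.
#'
#' @param mask Logical matrix.
#' @param radius Non-negative integer radius in pixels.
#' @return Logical matrix of the same shape.
#' @export
median_denoise <- function(mask, radius = 1) {
  mask <- as_mask(mask)
  if (radius < 0) stop("`radius` must be >= 0", call. = FALSE)
  radius <- as.integer(radius)
  if (radius == 0L) return(mask)
  w <- 2L * radius + 1L
  s <- neighborhood_sum(mask + 0, radius, pad_replicate(mask + 0, radius))
  s >= (w * w + 1) / 2
}

# Erosion / dilation with a k x k square element; outside the frame is
# background (erosion shrinks at the border, dilation never grows past it).
erode_square <- function(mask, k) {
  mask <- as_mask(mask)
  r <- (k - 1L) %/% 2L
  if (r == 0L) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L * r, nc + 2L * r)
  pad[(r + 1):(r + nr), (r + 1):(r + nc)] <- mask
  acc <- matrix(TRUE, nr, nc)
  for (dr in -r:r) for (dc in -r:r) {
    acc <- acc & pad[(1 + r + dr):(nr + r + dr), (1 + r + dc):(nc + r + dc)]
  }
  acc
}

dilate_square <- function(mask, k) {
  mask <- as_mask(mask)
  r <- (k - 1L) %/% 2L
  if (r == 0L) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L * r, nc + 2L * r)
  pad[(r + 1):(r + nr), (r + 1):(r + nc)] <- mask
  acc <- matrix(FALSE, nr, nc)
  for (dr in -r:r) for (dc in -r:r) {
    acc <- acc | pad[(1 + r + dr):(nr + r + dr), (1 + r + dc):(nc + r + dc)]
  }
  acc
}

#' Morphological opening of a plant mask
#'
#' Applies opening (erosion then dilation) with the configured square
#' structuring element, `morph_iterations` times. Opening removes
#' foreground specks smaller than the element while preserving the body
#' of blades wider than it.
#'
#' @param mask Logical matrix.
#' @param cfg A [seg_config()]; only `morph_size` and `morph_iterations`
#'   are used.
#' @return Logical matrix of the same shape.
#' @export
morphological_refine <- function(mask, cfg = seg_config()) {
  mask <- as_mask(mask)
  stopifnot(inherits(cfg, "seg_config"))
  for (i in seq_len(cfg$morph_iterations)) {
    mask <- dilate_square(erode_square(mask, cfg$morph_size), cfg$morph_size)
  }
  mask
}

# Propagate `reach` through TRUE cells of `domain` along maximal
# column-direction runs (column-major layout makes columns contiguous).
.fill_runs_cols <- function(reach, domain) {
  nr <- nrow(domain)
  v_d <- as.vector(domain)
  v_r <- as.vector(reach)
  start <- rep(FALSE, length(v_d))
  start[1L] <- TRUE
  start[-1L] <- v_d[-1L] != v_d[-length(v_d)]
  start[seq(1L, length(v_d), by = nr)] <- TRUE
  grp <- cumsum(start)
  hit <- rowsum(as.numeric(v_r), grp) > 0
  matrix(hit[grp] & v_d, nrow = nr)
}

#' Fill enclosed holes in a plant mask
#'
#' Background regions (4-connectivity) that cannot reach the image
#' border become foreground; border-connected background is untouched.
#' This restores blade interiors hollowed out by color thresholding.
#'
#' @param mask Logical matrix.
#' @return Logical matrix of the same shape.
#' @export
fill_holes <- function(mask) {
  mask <- as_mask(mask)
  bg <- !mask
  nr <- nrow(bg); nc <- ncol(bg)
  reach <- matrix(FALSE, nr, nc)
  reach[1, ] <- bg[1, ]; reach[nr, ] <- bg[nr, ]
  reach[, 1] <- bg[, 1]; reach[, nc] <- bg[, nc]
  repeat {
    nxt <- .fill_runs_cols(reach, bg)
    nxt <- t(.fill_runs_cols(t(nxt), t(bg)))
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  !reach
}

#' Label 8-connected foreground components
#'
#' @param mask Logical matrix.
#' @return Integer matrix; 0 is background, components are numbered from
#'   1 in scan order.
#' @export
label_components <- function(mask) {
  mask <- as_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx_fg <- which(mask)
  if (length(idx_fg) == 0L) return(lab)
  nlab <- 0L
  for (seed in idx_fg) {
    if (lab[seed] != 0L) next
    nlab <- nlab + 1L
    stack <- seed
    lab[seed] <- nlab
    while (length(stack) > 0L) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r0 <- ((cur - 1L) %% nr) + 1L
      c0 <- ((cur - 1L) %/% nr) + 1L
      rr <- max(1L, r0 - 1L):min(nr, r0 + 1L)
      cc <- max(1L, c0 - 1L):min(nc, c0 + 1L)
      nb <- as.vector(outer(rr, (cc - 1L) * nr, `+`))
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb) > 0L) {
        lab[nb] <- nlab
        stack <- c(stack, nb)
      }
    }
  }
  lab
}

#' Drop small foreground components from a mask
#'
#' @param mask Logical matrix.
#' @param min_area Minimum component pixel count (8-connectivity) to keep.
#' @return Logical matrix of the same shape.
#' @export
remove_small_components <- function(mask, min_area) {
  mask <- as_mask(mask)
  if (min_area <= 1L) return(mask)
  lab <- label_components(mask)
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  lab > 0L & matrix(lab %in% keep, nrow(lab), ncol(lab)) & mask
}

#' Segment a seedling image into a clean binary plant mask
#'
#' Full refinement chain: scaled channel stack, channel thresholding,
#' majority-median denoise, morphological opening, hole filling, and
#' removal of foreground components below `min_component_area`. The
#' result is deterministic for fixed inputs and configuration.
#'
#' @param img An [rgb_image()] (or coercible array).
#' @param cfg A [seg_config()].
#' @return Logical H x W plant mask.
#' @export
segment_plant <- function(img, cfg = seg_config()) {
  stopifnot(inherits(cfg, "seg_config"))
  stack <- build_channel_stack(img)
  mask <- channel_threshold_mask(stack, cfg)
  mask <- median_denoise(mask, cfg$median_radius)
  mask <- morphological_refine(mask, cfg)
  mask <- fill_holes(mask)
  remove_small_components(mask, cfg$min_component_area)
}
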