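# Trait extraction from binary plant masks.

TRAIT_VOCABULARY <- c("PH_px", "PH_mm", "AREA_px", "SL_mm", "FW_g")

#' Projected plant height of a mask, in pixels
#'
#' The inclusive vertical extent of the foreground: lowest foreground
#' row index minus highest foreground row index plus one, assuming an
#' upright camera with row 1 at the image top. This is the 2-D proxy for
#' shoot length measured from the ground to the longest leaf tip. An
#' empty mask yields 0 with a warning.
#'
#' @param mask Logical matrix.
#' @param soil_row Optional fixed soil-line row index; when given it
#'   replaces the bottom-most foreground row (useful when pots or soil
#'   are visible below the true base of the plant).
#' @return Integer height in pixels.
#' @export
projected_height <- function(mask, soil_row = NULL) {
  mask <- as_mask(mask)
  rows <- which(rowSums(mask) > 0)
  if (length(rows) == 0L) {
    warning("empty mask: projected height is 0", call. = FALSE)
    return(0L)
  }
  top <- min(rows)
  base <- if (is.null(soil_row)) max(rows) else as.integer(soil_row)
  if (base < top) return(0L)
  as.integer(base - top + 1L)
}

#' Projected pixel area of a mask
#'
#' @param mask Logical matrix.
#' @return Integer count of foreground pixels.
#' @export
pixel_area <- function(mask) {
  mask <- as_mask(mask)
  as.integer(sum(mask))
}

#' Convert a pixel height to millimetres
#'
#' @param height_px Height in pixels.
#' @param mm_per_px Positive scale factor (mm per pixel).
#' @return Height in millimetres.
#' @export
calibrate <- function(height_px, mm_per_px) {
  if (!is.finite(mm_per_px) || mm_per_px <= 0)
    stop("`mm_per_px` must be a positive finite number", call. = FALSE)
  height_px * mm_per_px
}

#' Extract image traits for a batch of plants
#'
#' Segments each image and records projected plant height (`PH_px`) and
#' pixel area (`AREA_px`), plus `PH_mm` when a calibration scale is
#' given. Images may be in-memory arrays or PNG file paths. A failure on
#' one image is reported, not fatal to the batch.
#'
#' @param images A list of entries, each a list with elements `line_id`,
#'   `replicate`, and `image` (an [rgb_image()]/array or a PNG path).
#'   `(line_id, replicate)` keys must be unique.
#' @param cfg A [seg_config()].
#' @param mm_per_px Optional positive calibration scale.
#' @return A data.frame with columns `line_id`, `replicate`, `trait`,
#'   `value`; failed images are listed in the `failures` attribute
#'   (data.frame of key and error message).
#' @export
extract_traits_batch <- function(images, cfg = seg_config(), mm_per_px = NULL) {
  stopifnot(is.list(images), inherits(cfg, "seg_config"))
  keys <- vapply(images, function(e) paste(e$line_id, e$replicate, sep = "\r"),
                 character(1))
  if (anyDuplicated(keys))
    stop("duplicate (line_id, replicate) keys in batch", call. = FALSE)
  rows <- list()
  fails <- list()
  for (e in images) {
    res <- tryCatch({
      img <- if (is.character(e$image)) read_image(e$image) else as_rgb_image(e$image)
      mask <- segment_plant(img, cfg)
      ph <- suppressWarnings(projected_height(mask))
      area <- pixel_area(mask)
      out <- data.frame(line_id = as.character(e$line_id),
                        replicate = as.integer(e$replicate),
                        trait = c("PH_px", "AREA_px"),
                        value = as.numeric(c(ph, area)),
                        stringsAsFactors = FALSE)
      if (!is.null(mm_per_px))
        out <- rbind(out, data.frame(line_id = as.character(e$line_id),
                                     replicate = as.integer(e$replicate),
                                     trait = "PH_mm",
                                     value = calibrate(ph, mm_per_px),
                                     stringsAsFactors = FALSE))
      out
    }, error = function(err) err)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        line_id = as.character(e$line_id), replicate = as.integer(e$replicate),
        message = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(line_id = character(), replicate = integer(),
               trait = character(), value = numeric(), stringsAsFactors = FALSE)
  attr(out, "failures") <- if (length(fails) > 0) do.call(rbind, fails) else NULL
  out
}

validate_trait_records <- function(records) {
  need <- c("line_id", "replicate", "trait", "value")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("trait records need columns line_id, replicate, trait, value",
         call. = FALSE)
  bad <- setdiff(unique(records$trait), TRAIT_VOCABULARY)
  if (length(bad) > 0)
    stop("unknown trait name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(!is.finite(records$value) | records$value < 0))
    stop("trait values must be finite and >= 0", call. = FALSE)
  key <- paste(records$line_id, records$replicate, records$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (line_id, replicate, trait) records", call. = FALSE)
  invisible(records)
}
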