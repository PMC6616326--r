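# File formats and configuration: PNG images and masks, CSV trait
# tables, genetic map + genotype CSVs, LOD profile / peak CSVs with
# replayable `#` headers, and YAML pipeline configuration.

#' Read an 8-bit RGB PNG as an RGB image
#'
#' Grayscale images are promoted to three identical channels and RGBA
#' alpha is dropped, each with a warning.
#'
#' @param path Path to a PNG file.
#' @return An [rgb_image()].
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop("image file not found: ", path, call. = FALSE)
  px <- tryCatch(png::readPNG(path),
                 error = function(e) stop("cannot read PNG '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  if (is.matrix(px)) {
    warning("grayscale PNG '", path, "' promoted to 3 identical channels",
            call. = FALSE)
    px <- array(rep(px, 3), dim = c(dim(px), 3))
  } else if (length(dim(px)) == 3L && dim(px)[3] == 4L) {
    warning("RGBA PNG '", path, "': alpha channel dropped", call. = FALSE)
    px <- px[, , 1:3, drop = FALSE]
  } else if (length(dim(px)) == 3L && dim(px)[3] == 2L) {
    warning("gray+alpha PNG '", path, "': alpha dropped, gray promoted",
            call. = FALSE)
    px <- array(rep(px[, , 1], 3), dim = c(dim(px)[1:2], 3))
  }
  rgb_image(round(px * 255))
}

#' Write an RGB image or a binary mask as PNG
#'
#' Masks are written as 0/255 grayscale.
#'
#' @param img An [rgb_image()] or array (for `write_image`); a logical
#'   matrix (for `write_mask`).
#' @param mask Logical matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_image <- function(img, path) {
  img <- as_rgb_image(img)
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' @rdname write_image
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' Write / read a trait record table as CSV
#'
#' Interchange format: header `line_id,replicate,trait,value`, UTF-8,
#' dot decimal, values serialized at 15 significant digits (lossless
#' well beyond 10 significant digits).
#'
#' @param records Trait records data.frame.
#' @param path CSV path.
#' @return `write_trait_table` returns the path invisibly;
#'   `read_trait_table` returns the validated records.
#' @export
write_trait_table <- function(records, path) {
  validate_trait_records(records)
  out <- records[, c("line_id", "replicate", "trait", "value")]
  out$value <- format(out$value, digits = 15, trim = TRUE, scientific = FALSE)
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trait_table
#' @export
read_trait_table <- function(path) {
  if (!file.exists(path)) stop("trait table not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L || lines[1] != "line_id,replicate,trait,value")
    stop("malformed trait table '", path,
         "': expected header line_id,replicate,trait,value", call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad) > 0)
    stop("malformed row at line ", bad[1] + 1L, " of '", path, "'", call. = FALSE)
  rec <- data.frame(
    line_id = vapply(parts, `[[`, "", 1L),
    replicate = suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L))),
    trait = vapply(parts, `[[`, "", 3L),
    value = suppressWarnings(as.numeric(vapply(parts, `[[`, "", 4L))),
    stringsAsFactors = FALSE)
  if (anyNA(rec$replicate) || anyNA(rec$value)) {
    bad <- which(is.na(rec$replicate) | is.na(rec$value))[1]
    stop("unparseable numeric field at line ", bad + 1L, " of '", path, "'",
         call. = FALSE)
  }
  validate_trait_records(rec)
  rec
}

#' Read a genetic map and a RIL genotype matrix from CSV
#'
#' The map CSV has columns `marker,chromosome,position_cM`; the genotype
#' CSV has a `line_id` column followed by one column per marker with
#' codes `A` (first parent), `B` (second parent) or `-` (missing).
#' Heterozygote codes `H` are recoded to missing with a counted warning
#' (RILs are treated as fully inbred). Marker order is taken from the
#' map file; markers present in one file but not the other raise an
#' error naming the offenders.
#'
#' @param map_path,geno_path CSV paths.
#' @return A list with `map` (data.frame) and `genotypes` (lines x
#'   markers numeric matrix, 1 = AA, 0 = BB, NA = missing).
#' @export
read_map_and_genotypes <- function(map_path, geno_path) {
  map <- utils::read.csv(map_path, stringsAsFactors = FALSE)
  need <- c("marker", "chromosome", "position_cM")
  if (!all(need %in% names(map)))
    stop("map CSV needs columns marker,chromosome,position_cM", call. = FALSE)
  map$chromosome <- as.character(map$chromosome)
  validate_genetic_map(map)
  gt <- utils::read.csv(geno_path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(gt)[1] != "line_id")
    stop("genotype CSV must start with a line_id column", call. = FALSE)
  gmk <- names(gt)[-1]
  missing_in_map <- setdiff(gmk, map$marker)
  missing_in_geno <- setdiff(map$marker, gmk)
  if (length(missing_in_map) > 0 || length(missing_in_geno) > 0)
    stop("marker mismatch between map and genotypes; ",
         "absent from map: ", paste(missing_in_map, collapse = ", "),
         "; absent from genotypes: ", paste(missing_in_geno, collapse = ", "),
         call. = FALSE)
  codes <- as.matrix(gt[, map$marker, drop = FALSE])
  n_het <- sum(codes == "H", na.rm = TRUE)
  if (n_het > 0)
    warning(n_het, " heterozygote call(s) recoded to missing", call. = FALSE)
  unknown <- setdiff(unique(as.vector(codes)), c("A", "B", "-", "H", NA))
  if (length(unknown) > 0)
    stop("unknown genotype code(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  geno <- matrix(NA_real_, nrow(codes), ncol(codes),
                 dimnames = list(gt$line_id, map$marker))
  geno[codes == "A"] <- 1
  geno[codes == "B"] <- 0
  list(map = map, genotypes = geno)
}

#' Write a genetic map / genotype matrix to CSV
#'
#' @param map Genetic map data.frame.
#' @param geno Numeric genotype matrix (1/0/NA).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_map_csv <- function(map, path) {
  validate_genetic_map(map)
  utils::write.table(map[, c("marker", "chromosome", "position_cM")], path,
                     sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_map_csv
#' @export
write_genotypes_csv <- function(geno, path) {
  codes <- matrix("-", nrow(geno), ncol(geno))
  codes[!is.na(geno) & geno == 1] <- "A"
  codes[!is.na(geno) & geno == 0] <- "B"
  df <- data.frame(line_id = rownames(geno), codes, stringsAsFactors = FALSE)
  names(df) <- c("line_id", colnames(geno))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Tiny djb2-style hash of a config object, for replayable digests.
config_digest <- function(x) {
  bytes <- utf8ToInt(paste(unlist(x), collapse = "\x1f"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

# Write a data.frame as CSV with replayable `#` header comment lines.
write_annotated_csv <- function(df, path, seed = NULL, digest = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# phenoscan %s",
                     as.character(utils::packageVersion("phenoscan"))), con)
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  if (!is.null(digest)) writeLines(sprintf("# config: %s", digest), con)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v)
    format(v, digits = 15, trim = TRUE, scientific = FALSE))
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_annotated_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Bundles the segmentation parameters, the optional mm-per-pixel
#' calibration, and the QTL scan settings. Round-trips losslessly
#' through YAML via [write_config()] / [read_config()].
#'
#' @param segmentation A [seg_config()].
#' @param mm_per_px Optional positive calibration scale (NULL = pixel
#'   units only).
#' @param step_cM Scan step in cM.
#' @param n_perm Number of permutations for the genome-wide threshold
#'   (the reference protocol uses 1000 at the 95% level).
#' @param alpha Genome-wide significance level.
#' @param drop_lod Support-interval LOD drop.
#' @param seed Default RNG seed for pipeline runs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(segmentation = seg_config(), mm_per_px = NULL,
                            step_cM = 1, n_perm = 1000, alpha = 0.05,
                            drop_lod = 1.5, seed = 1) {
  stopifnot(inherits(segmentation, "seg_config"))
  if (!is.null(mm_per_px) && (!is.finite(mm_per_px) || mm_per_px <= 0))
    stop("`mm_per_px` must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (step_cM <= 0) stop("`step_cM` must be > 0", call. = FALSE)
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)
  structure(
    list(segmentation = segmentation, mm_per_px = mm_per_px,
         qtl = list(step_cM = step_cM, n_perm = as.integer(n_perm),
                    alpha = alpha, drop_lod = drop_lod),
         seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg A [pipeline_config()].
#' @param path YAML path.
#' @return `write_config` returns the path invisibly; `read_config`
#'   returns the reconstructed `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  obj <- list(segmentation = unclass(cfg$segmentation),
              mm_per_px = cfg$mm_per_px, qtl = cfg$qtl, seed = cfg$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  s <- obj$segmentation
  pipeline_config(
    segmentation = seg_config(
      hue_window = as.numeric(s$hue_window), a_green_max = s$a_green_max,
      b_yellow_min = s$b_yellow_min, median_radius = s$median_radius,
      morph_size = s$morph_size, morph_iterations = s$morph_iterations,
      min_component_area = s$min_component_area),
    mm_per_px = obj$mm_per_px,
    step_cM = obj$qtl$step_cM, n_perm = obj$qtl$n_perm,
    alpha = obj$qtl$alpha, drop_lod = obj$qtl$drop_lod, seed = obj$seed)
}
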